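## Temporal revisit designs in McDonald notation, panel allocation along the
## spatially balanced order, and assembly of long-format survey data.

#' Parse a McDonald revisit-design notation
#'
#' Supported grammar: `"[1-0]"` (one panel visited every year), `"[1-b]"`
#' (1 + b serially alternating panels, each visited one year then rested b),
#' and `"[1-0,1-b]"` (an annual panel plus the alternating set). For the
#' augmented design the annual panel always holds 10 sites, so the annual
#' visit count `annual_n` must exceed 10 and each alternating panel holds
#' `annual_n - 10` sites.
#'
#' @param notation Design string, e.g. `"[1-0,1-3]"`.
#' @param annual_n Number of sites visited each year.
#' @param period_years Length of the monitoring period in years.
#' @param annual_panel_size Size of the always-revisit panel in the
#'   augmented design (default 10).
#' @param rotation_start 1-based index of the alternating panel visited in
#'   the first year (default 1).
#' @return An object of class `revisit_design`: a list with a `panels`
#'   data.frame (`panel_id`, `size`, `cycle`, `offset`), the period, and the
#'   notation.
#' @export
parse_revisit_design <- function(notation, annual_n, period_years = 12,
                                 annual_panel_size = 10,
                                 rotation_start = 1) {
  stopifnot(annual_n >= 1, period_years >= 1)
  s <- gsub(" ", "", notation)
  m <- regmatches(s, regexec("^\\[(\\d+)-(\\d+)(?:,(\\d+)-(\\d+))?\\]$", s))[[1]]
  if (length(m) == 0) stop("malformed revisit-design notation: ", notation)
  terms <- list(c(as.integer(m[2]), as.integer(m[3])))
  if (m[4] != "") terms <- c(terms, list(c(as.integer(m[4]), as.integer(m[5]))))
  for (tm in terms) {
    if (tm[1] != 1) stop("only single-visit panel terms [1-b] are supported: ", notation)
  }
  mk <- function(id, size, cycle, offset) {
    data.frame(panel_id = id, size = size, cycle = cycle, offset = offset)
  }
  if (length(terms) == 1) {
    rest <- terms[[1]][2]
    if (rest == 0) {
      panels <- mk(1L, annual_n, 1L, 0L)
    } else {
      cyc <- 1L + rest
      off <- (rotation_start - 1 + seq_len(cyc) - 1) %% cyc
      panels <- mk(seq_len(cyc), annual_n, cyc, as.integer(off))
    }
  } else {
    if (terms[[1]][2] != 0 || terms[[2]][2] == 0) {
      stop("augmented designs must combine an annual [1-0] panel with an alternating [1-b] set: ",
           notation)
    }
    if (annual_n <= annual_panel_size) {
      stop(sprintf("annual sample size %d must exceed the fixed annual panel of %d sites",
                   annual_n, annual_panel_size))
    }
    cyc <- 1L + terms[[2]][2]
    off <- (rotation_start - 1 + seq_len(cyc) - 1) %% cyc
    panels <- rbind(mk(1L, annual_panel_size, 1L, 0L),
                    mk(1L + seq_len(cyc), annual_n - annual_panel_size,
                       cyc, as.integer(off)))
  }
  structure(list(panels = panels, period_years = as.integer(period_years),
                 annual_n = as.integer(annual_n), notation = notation),
            class = "revisit_design")
}

#' Total unique sites a revisit design requires
#' @param design A [parse_revisit_design()] result.
#' @return Integer count.
#' @export
total_unique_sites <- function(design) {
  stopifnot(inherits(design, "revisit_design"))
  sum(design$panels$size)
}

#' Panel-level inclusion probability
#'
#' The probability that a site in a given panel is scheduled for measurement
#' in a given year: 1 for an annual panel and `1/c` for a serially
#' alternating panel with cycle length `c` (0.25 for a `[1-3]` set).
#'
#' @param design A [parse_revisit_design()] result.
#' @param panel_id Panel identifier.
#' @param year Location-shifted year value (0-based); must lie in the period.
#' @return The panel inclusion probability \eqn{\pi_{j|i}}.
#' @export
panel_inclusion_probability <- function(design, panel_id, year = 0) {
  stopifnot(inherits(design, "revisit_design"))
  row <- match(panel_id, design$panels$panel_id)
  if (is.na(row)) stop("unknown panel_id: ", panel_id)
  if (year < 0 || year >= design$period_years) stop("year outside monitoring period")
  1 / design$panels$cycle[row]
}

# Is a panel scheduled for measurement in (0-based) year x_j?
panel_visited <- function(design, panel_id, year) {
  row <- match(panel_id, design$panels$panel_id)
  (year %% design$panels$cycle[row]) == design$panels$offset[row]
}

#' Allocate an ordered sample draw to panels
#'
#' Panels are filled with contiguous blocks of the spatially balanced order
#' (annual panel first), so each panel is itself spatially balanced. Under a
#' stratified draw the contiguous-block allocation runs within each
#' stratum's own ordered list, with per-panel stratum shares apportioned by
#' largest remainder from the realized stratum sample sizes; the per-stratum
#' blocks are then merged per panel.
#'
#' @param draw A [grts_draw()] result.
#' @param design A [parse_revisit_design()] result.
#' @return The draw with an added `panel_id` column (unallocated oversample
#'   rows are dropped).
#' @export
allocate_panels <- function(draw, design) {
  stopifnot(inherits(draw, "sample_draw"), inherits(design, "revisit_design"))
  need <- total_unique_sites(design)
  sizes <- design$panels$size
  ids <- design$panels$panel_id
  # A stratified draw carries a per-stratum order; detect by repeated order 1.
  stratified <- sum(draw$order == 1) > 1
  if (!stratified) {
    if (nrow(draw) < need) {
      stop(sprintf("draw has %d sites but the design needs %d (shortfall %d)",
                   nrow(draw), need, need - nrow(draw)))
    }
    out <- draw[order(draw$order), , drop = FALSE][seq_len(need), , drop = FALSE]
    out$panel_id <- rep(ids, sizes)
  } else {
    nh <- table(draw$stratum)
    prop <- as.numeric(nh) / sum(nh)
    # per-panel stratum shares from the realized stratum allocation
    split_sizes <- vapply(sizes, function(sz) largest_remainder(sz, prop),
                          integer(length(nh)))
    if (is.null(dim(split_sizes))) split_sizes <- matrix(split_sizes, nrow = length(nh))
    rownames(split_sizes) <- names(nh)
    short <- rowSums(split_sizes) > as.numeric(nh)
    if (any(short)) {
      stop("draw shortfall in stratum: ", paste(names(nh)[short], collapse = ", "))
    }
    pieces <- lapply(names(nh), function(h) {
      sub <- draw[draw$stratum == h, , drop = FALSE]
      sub <- sub[order(sub$order), , drop = FALSE]
      take <- sum(split_sizes[h, ])
      sub <- sub[seq_len(take), , drop = FALSE]
      sub$panel_id <- rep(ids, split_sizes[h, ])
      sub
    })
    out <- do.call(rbind, pieces)
    out <- out[order(match(out$panel_id, ids), out$stratum, out$order), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("panel_assignment", class(draw))
  out
}

#' Assemble long-format survey data
#'
#' Joins the population response surface to the panel assignment under the
#' revisit schedule, producing one record per scheduled site-year with the
#' decomposed inclusion probabilities and the total design weight
#' \eqn{w_{ij} = 1/(\pi_i \pi_{j|i})}.
#'
#' @param responses Response matrix from [simulate_response()] (or any
#'   matrix with `site_id` rownames and year columns covering the period).
#' @param assignment An [allocate_panels()] result.
#' @param design The [parse_revisit_design()] used for the assignment.
#' @return A `data.frame` of class `survey_data` with columns `site_id`,
#'   `year`, `y`, `pi_site`, `pi_panel`, `weight`, `panel_id`, `stratum`,
#'   `cost_class`, `coord_x`, `coord_y`.
#' @export
assemble_survey <- function(responses, assignment, design) {
  stopifnot(inherits(assignment, "panel_assignment"),
            inherits(design, "revisit_design"))
  years <- as.numeric(colnames(responses))
  if (is.null(years) || anyNA(years)) years <- seq_len(ncol(responses)) - 1
  years <- years[seq_len(min(length(years), design$period_years))]
  if (length(years) < design$period_years) {
    stop("responses cover fewer years than the monitoring period")
  }
  rows <- match(as.character(assignment$site_id), rownames(responses))
  if (anyNA(rows)) stop("missing responses for sites: ",
                        paste(assignment$site_id[is.na(rows)], collapse = ", "))
  recs <- lapply(seq_along(years), function(j) {
    xj <- years[j]
    on_duty <- panel_visited(design, assignment$panel_id, xj)
    idx <- which(on_duty)
    if (!length(idx)) stop("no panel scheduled in year ", xj)
    pp <- 1 / design$panels$cycle[match(assignment$panel_id[idx], design$panels$panel_id)]
    data.frame(site_id = assignment$site_id[idx],
               year = xj,
               y = responses[rows[idx], j],
               pi_site = assignment$pi_i[idx],
               pi_panel = pp,
               weight = 1 / (assignment$pi_i[idx] * pp),
               panel_id = assignment$panel_id[idx],
               stratum = assignment$stratum[idx],
               cost_class = assignment$cost_class[idx],
               coord_x = assignment$x[idx],
               coord_y = assignment$y[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (anyNA(out$y)) stop("missing response for a scheduled visit")
  class(out) <- c("survey_data", "data.frame")
  out
}
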