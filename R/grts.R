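## Spatially balanced (GRTS-style) probability sampling of discrete frames.
##
## The draw uses recursive-quadrant hierarchical randomization: sites are
## mapped to a randomized 4-ary address on the unit square, a systematic
## pi-sample is taken along the randomized address order with a uniform
## start, and the selected sites are returned in reverse hierarchical order
## so that any contiguous prefix of the list is itself spatially balanced.

#' Describe a sample design
#'
#' @param kind One of `"equiprobable"`, `"stratified"`, `"unequal"`.
#' @param n Total number of unique sites to draw.
#' @param stratum_allocation Named proportions of `n` allocated per stratum
#'   (stratified designs); default 60% high / 40% low.
#' @param class_allocation Six cost-class effort shares (unequal designs);
#'   default 20/34/34/5/5/2 percent, low- to high-cost.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(kind = c("equiprobable", "stratified", "unequal"),
                          n,
                          stratum_allocation = c(high = 0.6, low = 0.4),
                          class_allocation = c(20, 34, 34, 5, 5, 2)) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  structure(list(kind = kind, n = as.integer(n),
                 stratum_allocation = normalize_props(stratum_allocation,
                                                      "stratum allocation"),
                 class_allocation = normalize_props(class_allocation,
                                                    "class allocation")),
            class = "sample_design")
}

#' First-stage inclusion probabilities for a design
#'
#' Computes \eqn{\pi_i} over the whole frame: `n/N` under an equiprobable
#' design; `n_h/N_h` within stratum under stratification (stratum sample
#' sizes by largest-remainder apportionment of the allocation); `n_c/N_c`
#' within travel-cost class under the unequal-probability design.
#'
#' @param frame A [build_frame()] result.
#' @param design A [sample_design()].
#' @return Numeric vector of inclusion probabilities aligned with `frame`
#'   rows; the per-stratum (or overall) sums equal the allocated sample
#'   sizes.
#' @export
inclusion_probabilities <- function(frame, design) {
  stopifnot(inherits(frame, "population_frame"), inherits(design, "sample_design"))
  N <- nrow(frame)
  n <- design$n
  pi_i <- numeric(N)
  if (design$kind == "equiprobable") {
    if (n > N) stop("sample size exceeds frame size")
    pi_i[] <- n / N
  } else if (design$kind == "stratified") {
    Nh <- stratum_sizes(frame)
    alloc <- design$stratum_allocation[names(Nh)]
    if (any(is.na(alloc))) stop("stratum allocation missing strata: ",
                                paste(setdiff(names(Nh), names(design$stratum_allocation)),
                                      collapse = ", "))
    nh <- largest_remainder(n, alloc)
    bad <- nh > Nh
    if (any(bad)) stop("stratified design infeasible (pi > 1) in stratum: ",
                       paste(names(Nh)[bad], collapse = ", "))
    for (h in seq_along(Nh)) {
      pi_i[frame$stratum == names(Nh)[h]] <- nh[h] / Nh[h]
    }
  } else {
    Nc <- tabulate(frame$cost_class, nbins = length(design$class_allocation))
    nc <- largest_remainder(n, design$class_allocation)
    present <- Nc > 0
    # every class with positive allocation keeps at least one slot, so no
    # site ends up unsampleable; the slot comes from the largest class
    needy <- which(nc == 0 & design$class_allocation > 0 & present)
    for (k in needy) {
      donor <- which.max(nc)
      if (nc[donor] <= 1) stop("sample too small to cover all allocated cost classes")
      nc[donor] <- nc[donor] - 1L
      nc[k] <- 1L
    }
    if (any(nc[!present] > 0)) stop("allocation assigns effort to empty cost class: ",
                                    paste(which(!present & nc > 0), collapse = ", "))
    bad <- present & nc > Nc
    if (any(bad)) stop("unequal design infeasible (pi > 1) in cost class: ",
                       paste(which(bad), collapse = ", "))
    for (k in which(present)) {
      pi_i[frame$cost_class == k] <- nc[k] / Nc[k]
    }
  }
  if (any(pi_i <= 0)) stop("design leaves some sites with zero inclusion probability")
  pi_i
}

# Randomized hierarchical address order of frame sites.  Returns the
# permutation of row indices ordering sites by a 4-ary quadrant address in
# which the quadrant labels are independently permuted within every parent
# cell (the hierarchical-randomization step).  Ties (co-addressed sites)
# break by site_id.
hierarchical_order <- function(x, y, site_id, nlevels = NULL) {
  N <- length(x)
  if (is.null(nlevels)) nlevels <- max(4L, ceiling(log(max(N, 2), 4)) + 2L)
  digits <- matrix(0L, N, nlevels)
  cx <- pmin(pmax(x, 0), 1 - 1e-12)
  cy <- pmin(pmax(y, 0), 1 - 1e-12)
  for (l in seq_len(nlevels)) {
    cx <- cx * 2; cy <- cy * 2
    qx <- floor(cx); qy <- floor(cy)
    digits[, l] <- as.integer(qx + 2 * qy)
    cx <- cx - qx; cy <- cy - qy
  }
  parent <- rep(0, N)            # address value of the enclosing cell
  value <- rep(0, N)             # randomized address value
  for (l in seq_len(nlevels)) {
    out_l <- integer(N)
    for (p in unique(parent)) {
      idx <- which(parent == p)
      perm <- sample.int(4L) - 1L
      out_l[idx] <- perm[digits[idx, l] + 1L]
    }
    value <- value * 4 + out_l
    parent <- value
  }
  order(value, site_id)
}

# Reverse-hierarchical ordering of k selected positions 0..k-1: write each in
# base 4, reverse the digits, and sort.  Guarantees prefixes of the final
# list spread over the address space.
reverse_hierarchical <- function(k) {
  if (k <= 1) return(seq_len(k))
  nd <- ceiling(log(k, 4))
  nd <- max(nd, 1L)
  idx <- 0:(k - 1)
  rev_val <- rep(0, k)
  v <- idx
  for (d in seq_len(nd)) {
    rev_val <- rev_val * 4 + (v %% 4)
    v <- v %/% 4
  }
  order(rev_val, idx)
}

# Core single-stratum draw: systematic pi-sampling along the randomized
# hierarchical order, then reverse-hierarchical ordering of the selections.
grts_draw_core <- function(frame, pi_i) {
  ord <- hierarchical_order(frame$x, frame$y, frame$site_id)
  pis <- pi_i[ord]
  cum <- cumsum(pis)
  n_target <- round(cum[length(cum)])
  if (abs(cum[length(cum)] - n_target) > 1e-8) {
    stop("inclusion probabilities must sum to an integer sample size")
  }
  u <- stats::runif(1)
  pts <- u + seq_len(n_target) - 1
  sel <- findInterval(pts, cum) + 1L
  sel <- sel[sel <= length(ord)]
  picked <- ord[sel]
  picked[reverse_hierarchical(length(picked))]
}

#' Draw a spatially balanced sample
#'
#' Draws sites with the supplied first-stage inclusion probabilities using
#' randomized hierarchical addressing and systematic \eqn{\pi}-sampling. The
#' returned site list is in reverse hierarchical order, so any contiguous
#' prefix is itself a spatially balanced subsample — the property panel
#' allocation relies on. Stratified designs are drawn independently within
#' stratum and returned with a per-stratum order column.
#'
#' @param frame A [build_frame()] result.
#' @param pi_i Inclusion probabilities from [inclusion_probabilities()].
#' @param stratify If `TRUE`, draw independently within each stratum
#'   (required for stratified designs).
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return A `data.frame` of class `sample_draw` with columns `order`
#'   (within stratum when `stratify`), `site_id`, `pi_i`, `stratum`,
#'   `cost_class`, `x`, `y`.
#' @export
grts_draw <- function(frame, pi_i, stratify = FALSE, seed = NULL) {
  stopifnot(inherits(frame, "population_frame"),
            length(pi_i) == nrow(frame))
  if (any(pi_i <= 0 | pi_i > 1 + 1e-12)) stop("inclusion probabilities must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pick_rows <- function(rows) {
    sub <- frame[rows, , drop = FALSE]
    class(sub) <- class(frame)
    idx <- grts_draw_core(sub, pi_i[rows])
    rows[idx]
  }
  if (stratify) {
    strata <- sort(unique(frame$stratum))
    picked <- lapply(strata, function(h) pick_rows(which(frame$stratum == h)))
    rows <- unlist(picked)
    ord <- unlist(lapply(picked, seq_along))
  } else {
    rows <- pick_rows(seq_len(nrow(frame)))
    ord <- seq_along(rows)
  }
  out <- data.frame(order = ord,
                    site_id = frame$site_id[rows],
                    pi_i = pi_i[rows],
                    stratum = frame$stratum[rows],
                    cost_class = frame$cost_class[rows],
                    x = frame$x[rows], y = frame$y[rows],
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_draw", "data.frame")
  out
}

#' Voronoi spatial-balance statistic
#'
#' Variance of the inclusion-probability totals over the Voronoi cells of a
#' point sample: every frame site contributes its \eqn{\pi_i} to its nearest
#' sampled site. For a perfectly balanced sample all cell totals equal 1, so
#' lower values indicate better spatial balance. Used to compare spatially
#' balanced draws against independent random sampling.
#'
#' @param frame A [build_frame()] result.
#' @param pi_i Frame-wide inclusion probabilities.
#' @param sample_rows Frame row indices of the sampled sites.
#' @return The variance of the Voronoi cell \eqn{\pi}-totals.
#' @export
voronoi_balance <- function(frame, pi_i, sample_rows) {
  stopifnot(length(sample_rows) >= 1)
  sx <- frame$x[sample_rows]; sy <- frame$y[sample_rows]
  d2 <- outer(frame$x, sx, "-")^2 + outer(frame$y, sy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  totals <- vapply(seq_along(sample_rows),
                   function(k) sum(pi_i[nearest == k]), numeric(1))
  stats::var(totals)
}
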