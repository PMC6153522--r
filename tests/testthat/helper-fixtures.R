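# Shared fixture builders; all randomness is seeded by the caller.

# Hand-built balanced long-format survey (every site visited every year),
# generated from the random-coefficients trend model.
make_balanced_survey <- function(n_sites = 20, n_years = 10,
                                 gamma0 = 1, gamma1 = 0.05,
                                 sigma_b = 0.1, sigma_a = 0.7,
                                 sigma_t = 0.02, sigma_e = 0.3,
                                 pi_site = 1, pi_panel = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(site_id = seq_len(n_sites), year = 0:(n_years - 1))
  a <- rnorm(n_sites, 0, sigma_a)
  t <- rnorm(n_sites, 0, sigma_t)
  b <- rnorm(n_years, 0, sigma_b)
  d$y <- gamma0 + gamma1 * d$year + a[d$site_id] + d$year * t[d$site_id] +
    b[d$year + 1] + rnorm(nrow(d), 0, sigma_e)
  d$pi_site <- pi_site
  d$pi_panel <- pi_panel
  d$weight <- 1 / (d$pi_site * d$pi_panel)
  d$panel_id <- 1L
  d$stratum <- "all"
  d$cost_class <- 1L
  cx <- runif(n_sites); cy <- runif(n_sites)
  d$coord_x <- cx[d$site_id]; d$coord_y <- cy[d$site_id]
  class(d) <- c("survey_data", "data.frame")
  d
}

# Full pipeline survey from the package generator (one replicate).
make_pipeline_survey <- function(design = "equiprobable", annual_n = 20,
                                 revisit = "[1-0]", period = 12,
                                 model = population_model(years = 0:(period - 1)),
                                 seed = 1) {
  set.seed(seed)
  frame <- build_frame(model = model)
  resp <- simulate_response(frame, model)
  rd <- parse_revisit_design(revisit, annual_n, period)
  des <- sample_design(design, n = total_unique_sites(rd))
  pis <- inclusion_probabilities(frame, des)
  draw <- grts_draw(frame, pis, stratify = design == "stratified")
  survey <- assemble_survey(resp, allocate_panels(draw, rd), rd)
  list(frame = frame, responses = resp, design = des, revisit = rd,
       survey = survey)
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))
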