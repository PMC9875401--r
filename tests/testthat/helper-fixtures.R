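# Shared fixtures: the packaged base case, cheap truncated variants, and
# degenerate configurations used by the engine/oracle tests.

.fixture_env <- new.env(parent = emptyenv())

base_params <- function() {
  if (is.null(.fixture_env$base)) {
    .fixture_env$base <- load_parameters(base_case_bundle())
  }
  .fixture_env$base
}

# base case truncated to a short horizon (cheap deterministic runs)
toy_params <- function(horizon_years = 3) {
  ps <- base_params()
  ps$structural$horizon_years$value <- horizon_years
  ps
}

# every event and death risk switched off; flat utility; no discounting
zero_risk_params <- function(utility = 0.81, horizon_years = 1) {
  ps <- toy_params(horizon_years)
  ps$tables$risk_grid[, -1] <- 0
  ps$tables$life_table$qx <- c(rep(0, nrow(ps$tables$life_table) - 1L), 1)
  for (cl in names(ps$clinical$bleed_risks)) {
    for (ev in names(ps$clinical$bleed_risks[[cl]])) {
      ps$clinical$bleed_risks[[cl]][[ev]]$value <- 0
    }
  }
  ps$economics$u_baseline$value <- utility
  ps$economics$u_af_decrement$value <- 0
  ps$economics$discount_rate_annual$value <- 0
  ps
}

# all distribution families collapsed to point masses (degenerate PSA)
point_mass_params <- function() {
  ps <- base_params()
  fix_node <- function(node) {
    for (nm in names(node)) {
      x <- node[[nm]]
      if (inherits(x, "icm_param")) {
        x$dist <- "fixed"
        node[[nm]] <- x
      } else if (is.list(x)) node[[nm]] <- fix_node(x)
    }
    node
  }
  for (g in c("clinical", "detection", "treatment", "economics", "structural")) {
    ps[[g]] <- fix_node(ps[[g]])
  }
  ps
}
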