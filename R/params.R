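#' @title Parameter bundles
#' @description Typed registry of every clinical, cost, utility and
#'   structural input of the model, loaded from a human-readable YAML
#'   bundle with provenance and uncertainty metadata, plus scenario
#'   override machinery.
#' @name params
#' @keywords internal
NULL

PARAM_GROUPS <- c("clinical", "detection", "treatment", "economics", "structural")

#' Normalise one bundle entry into a parameter leaf
#'
#' A leaf is a list with at least `value`; numeric scalars/vectors are
#' wrapped as fixed parameters. Character entries and NULLs are plain
#' settings and pass through untouched.
#' @noRd
as_param_leaf <- function(x) {
  if (is.null(x) || is.character(x)) return(x)
  if (is.list(x) && !is.null(x$value)) {
    leaf <- x
    if (is.list(leaf$value)) leaf$value <- unlist(leaf$value)
    if (is.null(leaf$dist)) {
      leaf$dist <- if (is.null(leaf$se) && is.null(leaf$sdlog)) "fixed" else "normal"
    }
    class(leaf) <- "icm_param"
    return(leaf)
  }
  if (is.numeric(x) || (is.list(x) && all(vapply(x, is.numeric, TRUE)))) {
    leaf <- list(value = unlist(x), dist = "fixed")
    class(leaf) <- "icm_param"
    return(leaf)
  }
  # nested group: recurse
  lapply(x, as_param_leaf)
}

is_param_leaf <- function(x) inherits(x, "icm_param")

#' Load a parameter bundle
#'
#' Reads a YAML scenario bundle plus the CSV tables it references
#' (stroke-risk grid, background life table, cumulative AF-detection
#' curve) and returns a validated parameter set.
#'
#' @param path Path to a bundle YAML file. Referenced CSVs are resolved
#'   relative to its directory.
#' @param validate_set If `TRUE` (default), abort on validation errors.
#' @return An object of class `icm_params`.
#' @export
load_parameters <- function(path, validate_set = TRUE) {
  if (!file.exists(path)) stop("parameter bundle not found: ", path)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(PARAM_GROUPS, names(raw))
  if (length(missing)) {
    stop("parameter bundle is missing required group(s): ",
         paste(missing, collapse = ", "))
  }
  ps <- list(
    meta = raw$meta,
    files = raw$files,
    dir = dirname(normalizePath(path))
  )
  for (g in PARAM_GROUPS) ps[[g]] <- lapply(raw[[g]], as_param_leaf)
  class(ps) <- "icm_params"
  ps <- attach_tables(ps)
  if (validate_set) {
    v <- validate(ps)
    if (nrow(v)) {
      stop("parameter bundle failed validation:\n",
           paste(sprintf("  %s: %s (observed %s)", v$parameter, v$rule, v$observed),
                 collapse = "\n"))
    }
  }
  ps
}

#' @noRd
attach_tables <- function(ps) {
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    p <- if (file.exists(f)) f else file.path(ps$dir, f)
    if (!file.exists(p)) stop("referenced table not found: ", f)
    p
  }
  ps$tables <- list()
  if (!is.null(ps$files$risk_grid)) {
    ps$tables$risk_grid <- read_risk_grid(resolve(ps$files$risk_grid))
  }
  if (!is.null(ps$files$life_table)) {
    ps$tables$life_table <- read_life_table(resolve(ps$files$life_table))
  }
  if (!is.null(ps$files$detection_curve)) {
    ps$tables$detection_curve <- read_detection_curve(resolve(ps$files$detection_curve))
  }
  ps
}

#' Read the annual ischemic-stroke risk grid
#'
#' CSV mirroring the published table layout: one row per CHADS2 score,
#' columns for no-AF and subclinical-AF crossed with treatment
#' (probabilities as fractions, not percent).
#' @param path CSV path.
#' @return data.frame with column `chads2` and six risk columns.
#' @export
read_risk_grid <- function(path) {
  g <- utils::read.csv(path, check.names = FALSE)
  need <- c("chads2", "noaf_none", "noaf_aspirin", "subaf_none",
            "subaf_aspirin", "subaf_noac", "subaf_warfarin")
  if (!all(need %in% names(g))) {
    stop("risk grid must have columns: ", paste(need, collapse = ", "))
  }
  g[order(g$chads2), need]
}

#' Read a life table (age, annual death probability)
#' @param path CSV path with columns `age`, `qx`.
#' @return data.frame ordered by age.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) stop("life table needs columns age, qx")
  lt <- lt[order(lt$age), ]
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  lt
}

#' Read a cumulative AF-detection curve
#' @param path Two-column CSV (`month`, `cumulative`).
#' @return A `detection_curve` (see [detection_curve()]).
#' @export
read_detection_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("month", "cumulative") %in% names(d))) {
    stop("detection curve needs columns month, cumulative")
  }
  detection_curve(d$month, d$cumulative)
}

#' Fetch a parameter leaf by dotted path
#' @param ps An `icm_params` object.
#' @param path Dotted path, e.g. `"economics.cost_noac_cycle"`.
#' @return The leaf (an `icm_param`) or plain setting.
#' @export
param_leaf <- function(ps, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- ps
  for (p in parts) {
    if (is.null(node[[p]])) stop("unknown parameter path: ", path)
    node <- node[[p]]
  }
  node
}

#' Fetch a parameter value by dotted path
#' @inheritParams param_leaf
#' @return Numeric value(s) for parameter leaves; raw value for settings.
#' @export
param_value <- function(ps, path) {
  leaf <- param_leaf(ps, path)
  if (is_param_leaf(leaf)) leaf$value else leaf
}

#' Scenario specification
#'
#' @param name Scenario identifier.
#' @param overrides Named list, dotted parameter path -> new value. A
#'   numeric value replaces the leaf's `value`; a character value
#'   replaces a plain setting (e.g. `detection.extrapolation`,
#'   `files.detection_curve`).
#' @param description Optional free text.
#' @return An object of class `icm_scenario`.
#' @export
scenario_spec <- function(name, overrides = list(), description = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, overrides = overrides, description = description),
            class = "icm_scenario")
}

#' Apply scenario overrides to a parameter set
#'
#' Returns a new, re-validated parameter set; fields not named in the
#' overrides are untouched. Unknown paths raise an error naming the path.
#'
#' @param base An `icm_params` object.
#' @param spec An `icm_scenario` (or bare named list of overrides).
#' @return A new `icm_params`.
#' @export
apply_overrides <- function(base, spec) {
  overrides <- if (inherits(spec, "icm_scenario")) spec$overrides else spec
  ps <- base
  reload_tables <- FALSE
  for (path in names(overrides)) {
    val <- overrides[[path]]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    # verify the path resolves before touching anything
    node <- ps
    for (p in parts) {
      if (is.null(node[[p]])) stop("override path does not resolve: ", path)
      node <- node[[p]]
    }
    if (is_param_leaf(node)) {
      if (!is.numeric(val)) stop("override for ", path, " must be numeric")
      node$value <- val
      ps[[parts]] <- node
    } else {
      ps[[parts]] <- val
      if (parts[1] == "files") reload_tables <- TRUE
    }
  }
  if (reload_tables) ps <- attach_tables(ps)
  v <- validate(ps)
  if (nrow(v)) {
    stop("overridden parameter set failed validation:\n",
         paste(sprintf("  %s: %s", v$parameter, v$rule), collapse = "\n"))
  }
  ps
}

#' @noRd
flatten_leaves <- function(node, prefix = character()) {
  out <- list()
  for (nm in names(node)) {
    x <- node[[nm]]
    path <- c(prefix, nm)
    if (is_param_leaf(x)) {
      out[[paste(path, collapse = ".")]] <- x
    } else if (is.list(x)) {
      out <- c(out, flatten_leaves(x, path))
    }
  }
  out
}

#' Flatten a parameter set to a provenance table
#'
#' @param ps An `icm_params` object.
#' @return data.frame with one row per scalar parameter: path, value,
#'   se, distribution family, source citation tag and review marker.
#' @export
flatten_parameters <- function(ps) {
  leaves <- flatten_leaves(ps[PARAM_GROUPS], prefix = character())
  rows <- lapply(names(leaves), function(nm) {
    lf <- leaves[[nm]]
    vals <- lf$value
    idx <- if (length(vals) > 1L) paste0(nm, "[", seq_along(vals), "]") else nm
    data.frame(
      parameter = idx, value = as.numeric(vals),
      se = if (is.null(lf$se)) NA_real_ else lf$se,
      sdlog = if (is.null(lf$sdlog)) NA_real_ else lf$sdlog,
      dist = lf$dist,
      type = if (is.null(lf$type)) NA_character_ else lf$type,
      source = if (is.null(lf$source)) NA_character_ else lf$source,
      review = if (is.null(lf$review)) NA_character_ else lf$review,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Validate a parameter set
#'
#' Reports every invariant violation: type bounds (probabilities in
#' \[0,1\], utilities in \[-1,1\], costs and ratios nonnegative),
#' simplexes summing to 1, hazard ratio above 1, cycle length positive,
#' and the fixed-distribution default when no uncertainty is given.
#'
#' @param ps An `icm_params` object.
#' @return data.frame of violations (zero rows when valid) with columns
#'   `parameter`, `rule`, `observed`.
#' @export
validate <- function(ps) {
  bad <- list()
  note <- function(parameter, rule, observed) {
    bad[[length(bad) + 1L]] <<- data.frame(
      parameter = parameter, rule = rule,
      observed = paste(signif(as.numeric(observed), 6), collapse = ", "),
      stringsAsFactors = FALSE)
  }
  leaves <- flatten_leaves(ps[PARAM_GROUPS])
  for (nm in names(leaves)) {
    lf <- leaves[[nm]]
    v <- lf$value
    type <- if (is.null(lf$type)) NA_character_ else lf$type
    if (!all(is.finite(v))) { note(nm, "non-finite value", v); next }
    if (identical(type, "probability") && any(v < 0 | v > 1)) {
      note(nm, "probability outside [0, 1]", v)
    }
    if (identical(type, "utility") && any(v < -1 | v > 1)) {
      note(nm, "utility outside [-1, 1]", v)
    }
    if (identical(type, "cost") && any(v < 0)) note(nm, "negative cost", v)
    if (identical(type, "ratio") && any(v <= 0)) note(nm, "ratio not positive", v)
    if (identical(type, "years") && any(v <= 0)) note(nm, "years not positive", v)
    if (identical(type, "simplex") && abs(sum(v) - 1) > 1e-6) {
      note(nm, "components do not sum to 1", sum(v))
    }
    if (!is.null(lf$se) && lf$se < 0) note(nm, "negative se", lf$se)
    if (is.null(lf$se) && is.null(lf$sdlog) && !identical(lf$dist, "fixed")) {
      note(nm, "no uncertainty given but dist is not fixed", NA)
    }
  }
  hr <- tryCatch(param_value(ps, "detection.hr_icm_vs_soc"), error = function(e) NULL)
  if (!is.null(hr) && hr <= 1) note("detection.hr_icm_vs_soc", "hazard ratio must exceed 1", hr)
  cm <- tryCatch(param_value(ps, "structural.cycle_months"), error = function(e) NULL)
  if (!is.null(cm) && cm <= 0) note("structural.cycle_months", "cycle length must be positive", cm)
  if (!is.null(ps$tables$risk_grid)) {
    rg <- ps$tables$risk_grid
    probs <- as.matrix(rg[, -1])
    if (any(probs < 0 | probs > 1)) note("tables.risk_grid", "annual probability outside [0, 1]", range(probs))
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(parameter = character(), rule = character(), observed = character(),
               stringsAsFactors = FALSE)
}

#' Write a parameter set back to a bundle directory
#'
#' Emits the YAML bundle plus the referenced CSV tables so that
#' `load_parameters()` on the result round-trips every field.
#'
#' @param ps An `icm_params` object.
#' @param dir Output directory (created if needed).
#' @param name Bundle file name (default `bundle.yaml`).
#' @return Invisibly, the path to the written YAML.
#' @export
write_parameters <- function(ps, dir, name = "bundle.yaml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(node) {
    if (is_param_leaf(node)) return(unclass(node))
    if (is.list(node)) return(lapply(node, strip))
    node
  }
  out <- c(list(meta = ps$meta, files = ps$files),
           lapply(ps[PARAM_GROUPS], strip))
  path <- file.path(dir, name)
  yaml::write_yaml(out, path, precision = 15)
  if (!is.null(ps$tables$risk_grid)) {
    utils::write.csv(ps$tables$risk_grid, file.path(dir, ps$files$risk_grid),
                     row.names = FALSE)
  }
  if (!is.null(ps$tables$life_table)) {
    utils::write.csv(ps$tables$life_table, file.path(dir, ps$files$life_table),
                     row.names = FALSE)
  }
  if (!is.null(ps$tables$detection_curve)) {
    dc <- ps$tables$detection_curve
    utils::write.csv(data.frame(month = dc$month, cumulative = dc$cumulative),
                     file.path(dir, ps$files$detection_curve), row.names = FALSE)
  }
  invisible(path)
}

#' Path of the packaged base-case bundle
#' @param name Bundle file name within `inst/extdata`.
#' @return Absolute path.
#' @export
base_case_bundle <- function(name = "base_case.yaml") {
  system.file("extdata", name, package = "icmcea", mustWork = TRUE)
}
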