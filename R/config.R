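#' Load a run configuration from YAML
#'
#' A run configuration gathers every tunable in one validated document:
#' the global `seed` (mandatory), the `calendar` block, the prompt
#' `schedule` block (waking window, minimum gap), the `risk` block (see
#' [risk_config()]), the `sim` block (see [sim_config()]), the
#' `compensation` block (see [compensation_rule()]) and a `paths` block
#' (message bank, output directory).  Unknown keys anywhere are rejected;
#' omitted keys take the documented defaults.
#'
#' @param path Path to a YAML file, or a list already in that shape.
#' @return An object of class `run_config` with fully applied defaults.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  known <- c("seed", "calendar", "schedule", "risk", "sim",
             "compensation", "paths")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("load_config: unknown key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$seed)) stop("load_config: 'seed' is required")
  seed <- as.integer(raw$seed)

  cal_block <- check_block(raw$calendar, "calendar", "baseline_day")
  cal <- study_calendar(baseline_day = cal_block$baseline_day %||% 0L)

  sch <- check_block(raw$schedule, "schedule", c("window", "min_gap"))
  schedule <- list(window = as.numeric(sch$window %||% c(8 * 60, 22 * 60)),
                   min_gap = as.numeric(sch$min_gap %||% 40))

  rk <- check_block(raw$risk, "risk",
                    c("weights", "risk_threshold", "likelihood_threshold",
                      "likelihood_scope", "trigger_priority"))
  rk_defaults <- risk_config()
  risk <- risk_config(
    weights = unlist(rk$weights %||% rk_defaults$weights),
    risk_threshold = rk$risk_threshold %||% rk_defaults$risk_threshold,
    likelihood_threshold = rk$likelihood_threshold %||%
      rk_defaults$likelihood_threshold,
    likelihood_scope = rk$likelihood_scope %||% rk_defaults$likelihood_scope,
    trigger_priority = unlist(rk$trigger_priority %||%
                                rk_defaults$trigger_priority))

  sim_known <- setdiff(names(formals(sim_config)), c("risk", "seed"))
  sm <- check_block(raw$sim, "sim", sim_known)
  for (nm in c("likert_mu", "likert_sigma"))
    if (!is.null(sm[[nm]])) sm[[nm]] <- unlist(sm[[nm]])
  sim <- do.call(sim_config, c(sm, list(risk = risk, seed = seed)))

  cp <- check_block(raw$compensation, "compensation",
                    c("visit_payments", "ema_tiers"))
  comp_args <- list()
  if (!is.null(cp$visit_payments))
    comp_args$visit_payments <- unlist(cp$visit_payments)
  if (!is.null(cp$ema_tiers))
    comp_args$ema_tiers <- as.data.frame(do.call(rbind,
      lapply(cp$ema_tiers, as.data.frame)))
  comp <- do.call(compensation_rule, comp_args)

  pt <- check_block(raw$paths, "paths", c("bank", "out_dir"))

  structure(
    list(seed = seed, cal = cal, schedule = schedule, risk = risk,
         sim = sim, compensation = comp,
         paths = list(bank = pt$bank, out_dir = pt$out_dir %||% "jitair-run")),
    class = "run_config"
  )
}

check_block <- function(block, name, known) {
  if (is.null(block)) return(list())
  bad <- setdiff(names(block), known)
  if (length(bad))
    stop("load_config: unknown key(s) in '", name, "': ",
         paste(bad, collapse = ", "))
  block
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise the effective configuration
#'
#' Dumps a [load_config()] result back to the YAML shape it was loaded
#' from, with all defaults made explicit, so that load -> dump -> load is
#' the identity on effective configurations and the dump can serve as a
#' provenance record.
#'
#' @param config A `run_config`.
#' @param path Optional file to write; when `NULL` the YAML string is
#'   returned.
#' @return YAML string, or `path` invisibly when written.
#' @export
dump_config <- function(config, path = NULL) {
  sim <- unclass(config$sim)
  sim$risk <- NULL
  sim$seed <- NULL
  doc <- list(
    seed = config$seed,
    calendar = list(baseline_day = config$cal$baseline_day),
    schedule = config$schedule,
    risk = list(weights = as.list(config$risk$weights),
                risk_threshold = config$risk$risk_threshold,
                likelihood_threshold = config$risk$likelihood_threshold,
                likelihood_scope = config$risk$likelihood_scope,
                trigger_priority = config$risk$trigger_priority),
    sim = lapply(sim, function(x) if (length(names(x))) as.list(x) else x),
    compensation = list(
      visit_payments = as.list(config$compensation$visit_payments),
      ema_tiers = lapply(seq_len(nrow(config$compensation$ema_tiers)),
                         function(i) as.list(config$compensation$ema_tiers[i, ]))),
    paths = config$paths
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
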