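#' The fixed toy-example encoders
#'
#' Direct: `{1,4} -> 0, {2,3} -> 1` on both axes (groups states by their
#' row/column affordance expectation). Indirect: `{1,2} -> 0, {3,4} -> 1`
#' (groups states by coarse position).
#'
#' @param strategy `"direct"` or `"indirect"`.
#' @return A list of two [encoder_map()]s (`b`, `c`).
#' @export
toy_encoders <- function(strategy = c("direct", "indirect")) {
  strategy <- match.arg(strategy)
  a <- if (strategy == "direct") c(0L, 1L, 1L, 0L) else c(0L, 0L, 1L, 1L)
  list(b = encoder_map(a, 2), c = encoder_map(a, 2))
}

#' Reproduce the toy example end to end
#'
#' Evaluates the fixed direct and indirect encoders on the toy landscape
#' (the six headline metrics per strategy), then independently re-derives
#' both strategies by hill climbing and certifies the indirect optimum by
#' exhaustive search over all 256 encoder pairs.
#'
#' @param seed seed for the hill-climbing re-derivation.
#' @return A list of class `toy_report`: `direct` and `indirect`
#'   [metrics_report()]s for the fixed encoders, `optimized` (hill-climb
#'   results), `oracle` (exhaustive indirect search), and `status`
#'   (`"ok"` or `"mismatch"` against the expected fixed-encoder metrics).
#' @export
run_toy <- function(seed = 1) {
  land <- toy_landscape()
  reports <- lapply(c("direct", "indirect"), function(s) {
    enc <- toy_encoders(s)
    metrics_report(land, build_decoder(land, enc$b, enc$c))
  })
  names(reports) <- c("direct", "indirect")
  opt_direct <- optimize_strategy(land, "direct", L_B = 2, L_C = 2,
                                  runs = 20, steps = 200, seed = seed)
  opt_indirect <- optimize_strategy(land, "indirect", L_B = 2, L_C = 2,
                                    runs = 20, steps = 200, seed = seed)
  oracle <- exhaustive_search(function(enc) {
    mse_indirect_fast(enc[[1]] + 1L, 2L, enc[[2]] + 1L, 2L, land$matrix)
  }, n_obs = c(4, 4), L = c(2, 2))
  expected <- list(
    direct = c(mse = 7 / 16, synergy = 0.25, mi_ob = 0, mi_oc = 0,
               mi_ab = 1, mi_ac = 1),
    indirect = c(mse = 3 / 32, synergy = 1, mi_ob = 1, mi_oc = 1,
                 mi_ab = 0, mi_ac = 0))
  ok <- TRUE
  for (s in names(reports)) {
    r <- reports[[s]]
    got <- c(r$mse_affordance, r$synergy, r$mi_sensory_b, r$mi_sensory_c,
             r$mi_unidim_b, r$mi_unidim_c)
    tol <- c(1e-9, 1e-2, 1e-9, 1e-9, 1e-9, 1e-9)
    if (any(abs(got - expected[[s]]) > tol)) ok <- FALSE
  }
  structure(list(direct = reports$direct, indirect = reports$indirect,
                 optimized = list(direct = opt_direct,
                                  indirect = opt_indirect),
                 oracle = oracle,
                 status = if (ok) "ok" else "mismatch"),
            class = "toy_report")
}

#' @export
print.toy_report <- function(x, ...) {
  fmt <- function(r) {
    sprintf("%.2f\t%.2f\t%g\t%g\t%g\t%g",
            r$mse_affordance, r$synergy,
            round(r$mi_sensory_b, 2), round(r$mi_sensory_c, 2),
            round(r$mi_unidim_b, 2), round(r$mi_unidim_c, 2))
  }
  cat("Strategy\tMSE(A,Ahat)\tsynergy\tI(OB;OBhat)\tI(OC;OChat)",
      "\tI(AB;ABhat)\tI(AC;AChat)\n", sep = "")
  cat("Direct\t", fmt(x$direct), "\n", sep = "")
  cat("Indirect\t", fmt(x$indirect), "\n", sep = "")
  cat(sprintf("status: %s (indirect exhaustive optimum %.5f)\n",
              x$status, x$oracle$best_value))
  invisible(x)
}

#' Batch experiment configuration
#'
#' @param kind landscape generator kind (see [generate_landscape()]).
#' @param m,n,levels,noise,blocks generator parameters.
#' @param L_B,L_C signal counts per encoder (default 8, i.e. 3 bits).
#' @param n_landscapes number of landscapes.
#' @param runs,steps hill-climbing budget per strategy per landscape.
#' @param base_seed integer; all per-landscape seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(kind = "blobs", m = 32, n = 32, levels = 5,
                              noise = 0, blocks = 2, L_B = 8, L_C = 8,
                              n_landscapes = 30, runs = 10, steps = 3000,
                              base_seed = 1) {
  if (n_landscapes < 1) stop("at least one landscape is required")
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the batch strategy-comparison experiment
#'
#' For each of `n_landscapes` seeded synthetic landscapes, both encoding
#' strategies are optimized by hill climbing and scored with
#' [metrics_report()]. The report pairs the strategies per landscape and
#' tests the two directional hypotheses (indirect attains lower affordance
#' MSE; indirect attains higher synergy) with one-sided paired Wilcoxon
#' signed-rank tests.
#'
#' @param config an [experiment_config()].
#' @param progress if `TRUE`, print one line per landscape per strategy.
#' @return A list of class `experiment_report` with `records` (data frame,
#'   two rows per landscape), `summary`, and `config`.
#' @export
run_batch <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  records <- vector("list", 2L * config$n_landscapes)
  for (i in seq_len(config$n_landscapes)) {
    seed_i <- config$base_seed + 1000L * i
    land <- generate_landscape(config$kind, config$m, config$n,
                               levels = config$levels, noise = config$noise,
                               blocks = config$blocks, seed = seed_i)
    for (s in c("direct", "indirect")) {
      t0 <- proc.time()[["elapsed"]]
      opt <- optimize_strategy(land, s, config$L_B, config$L_C,
                               runs = config$runs, steps = config$steps,
                               seed = seed_i + (s == "indirect"))
      rec <- tryCatch({
        met <- metrics_report(
          land, build_decoder(land, opt$encoder_b, opt$encoder_c))
        data.frame(landscape = i, seed = seed_i, strategy = s,
                   mse_affordance = met$mse_affordance,
                   synergy = met$synergy,
                   mi_sensory_b = met$mi_sensory_b,
                   mi_sensory_c = met$mi_sensory_c,
                   mi_unidim_b = met$mi_unidim_b,
                   mi_unidim_c = met$mi_unidim_c,
                   mse_sensory_b = met$mse_sensory_b,
                   mse_sensory_c = met$mse_sensory_c,
                   spatial_entropy_b = met$spatial_entropy_b,
                   spatial_entropy_c = met$spatial_entropy_c,
                   failed = FALSE)
      }, error = function(e) {
        warning(sprintf("landscape %d (%s): PID failure: %s",
                        i, s, conditionMessage(e)))
        data.frame(landscape = i, seed = seed_i, strategy = s,
                   mse_affordance = NA_real_, synergy = NA_real_,
                   mi_sensory_b = NA_real_, mi_sensory_c = NA_real_,
                   mi_unidim_b = NA_real_, mi_unidim_c = NA_real_,
                   mse_sensory_b = NA_real_, mse_sensory_c = NA_real_,
                   spatial_entropy_b = NA_real_,
                   spatial_entropy_c = NA_real_, failed = TRUE)
      })
      if (progress) {
        cat(sprintf("landscape %d %-8s seed %d objective %.4f synergy %s (%.1fs)\n",
                    i, s, seed_i, rec$mse_affordance,
                    format(rec$synergy, digits = 3),
                    proc.time()[["elapsed"]] - t0))
      }
      records[[2L * (i - 1L) + (s == "indirect") + 1L]] <- rec
    }
  }
  records <- do.call(rbind, records)
  report <- structure(list(records = records,
                           summary = summarize_batch(records),
                           config = unclass(config),
                           schema_version = 1L),
                      class = "experiment_report")
  report
}

summarize_batch <- function(records) {
  ok <- !records$failed
  keep <- records$landscape %in%
    intersect(records$landscape[ok & records$strategy == "direct"],
              records$landscape[ok & records$strategy == "indirect"])
  d <- records[keep & records$strategy == "direct", ]
  ind <- records[keep & records$strategy == "indirect", ]
  d <- d[order(d$landscape), ]; ind <- ind[order(ind$landscape), ]
  mse_test <- stats::wilcox.test(ind$mse_affordance, d$mse_affordance,
                                 paired = TRUE, alternative = "less",
                                 exact = FALSE)
  syn_test <- stats::wilcox.test(ind$synergy, d$synergy, paired = TRUE,
                                 alternative = "greater", exact = FALSE)
  list(n_paired = nrow(d),
       n_excluded = sum(records$failed),
       mean_mse = c(direct = mean(d$mse_affordance),
                    indirect = mean(ind$mse_affordance)),
       mean_synergy = c(direct = mean(d$synergy),
                        indirect = mean(ind$synergy)),
       frac_indirect_lower_mse =
         mean(ind$mse_affordance < d$mse_affordance),
       frac_indirect_higher_synergy = mean(ind$synergy > d$synergy),
       p_mse = mse_test$p.value,
       p_synergy = syn_test$p.value)
}

#' @export
print.experiment_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("batch experiment: %d paired landscapes (%d excluded)\n",
              s$n_paired, s$n_excluded))
  cat(sprintf("  affordance MSE: direct %.4f vs indirect %.4f (p = %.3g)\n",
              s$mean_mse["direct"], s$mean_mse["indirect"], s$p_mse))
  cat(sprintf("  synergy: direct %.4f vs indirect %.4f (p = %.3g)\n",
              s$mean_synergy["direct"], s$mean_synergy["indirect"],
              s$p_synergy))
  invisible(x)
}

#' Write / read an experiment report
#'
#' `report.json` carries the whole report (schema-versioned); `records.csv`
#' carries the per-landscape table. The pair round-trips losslessly up to
#' numeric serialization.
#'
#' @param report an `experiment_report`.
#' @param directory output directory (created if missing).
#' @return `read_report` returns the `experiment_report`.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
    message(sprintf("created output directory %s", directory))
  }
  jsonlite::write_json(unclass(report),
                       file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.csv(report$records, file.path(directory, "records.csv"),
                   row.names = FALSE)
  invisible(directory)
}

#' @rdname write_report
#' @export
read_report <- function(directory) {
  obj <- jsonlite::read_json(file.path(directory, "report.json"),
                             simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop(sprintf("unsupported report schema version: %s",
                 format(obj$schema_version)))
  }
  obj$records <- as.data.frame(obj$records)
  obj$summary$mean_mse <- unlist(obj$summary$mean_mse)
  obj$summary$mean_synergy <- unlist(obj$summary$mean_synergy)
  structure(obj, class = "experiment_report")
}
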