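# Temperature replica-exchange (T-REMD) protocol arithmetic: arithmetic
# ladder design, exchange-attempt scheduling and acceptance statistics from
# swap logs.  The MD engine itself is never invoked; engine settings are
# carried as opaque protocol metadata only.

#' Build an arithmetic temperature ladder
#'
#' `temperatures[k] = t_min + k * delta_t`, `k = 0..n-1`. Uniform-spacing
#' ladders are the canonical protocol here; geometric ladders are a common
#' alternative but are not generated by this function.
#'
#' @param t_min Lowest (reference) temperature, K.
#' @param n_replicas Number of replicas (>= 1).
#' @param delta_t Temperature step, K (> 0).
#' @return Object of class `temperature_ladder`: `temperatures`
#'   (ascending), `n_replicas`, `delta_t`, `t_min`, `t_max`.
#' @examples
#' build_ladder(310.15, 10, 2.34)$t_max  # 331.21 K
#' @export
build_ladder <- function(t_min, n_replicas, delta_t) {
  if (t_min <= 0) stop("t_min must be positive (Kelvin)")
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (delta_t <= 0) stop("delta_t must be positive")
  temps <- t_min + (seq_len(n_replicas) - 1) * delta_t
  out <- list(temperatures = temps, n_replicas = n_replicas,
              delta_t = delta_t, t_min = temps[1],
              t_max = temps[n_replicas])
  class(out) <- "temperature_ladder"
  out
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("T-REMD ladder: %d replicas, %.2f K to %.2f K (dT = %.2f K)\n",
              x$n_replicas, x$t_min, x$t_max, x$delta_t))
  invisible(x)
}

#' Construct an exchange log
#'
#' @param records Data frame with columns `attempt` (integer attempt
#'   index), `pair_lo` (lower replica index of the adjacent pair) and
#'   `accepted` (logical or 0/1).
#' @param attempt_interval_steps MD steps between exchange attempts.
#' @param timestep_fs Integration timestep, fs.
#' @param n_replicas Optional replica count for validating pair indices.
#' @return Object of class `exchange_log`.
#' @export
exchange_log <- function(records, attempt_interval_steps = 500,
                         timestep_fs = 2, n_replicas = NULL) {
  stopifnot(is.data.frame(records),
            all(c("attempt", "pair_lo", "accepted") %in% names(records)))
  if (nrow(records) < 1) stop("empty exchange log")
  records$accepted <- as.logical(records$accepted)
  if (anyNA(records$accepted)) stop("`accepted` must be logical or 0/1")
  if (!is.null(n_replicas) && any(records$pair_lo >= n_replicas)) {
    stop("pair_lo must index adjacent pairs (1..n_replicas-1)")
  }
  out <- list(records = records,
              attempt_interval_steps = attempt_interval_steps,
              timestep_fs = timestep_fs)
  class(out) <- "exchange_log"
  out
}

#' Read an exchange log from TSV
#'
#' Expects the columns `attempt`, `pair_lo`, `accepted`.
#'
#' @param path TSV path.
#' @inheritParams exchange_log
#' @return An `exchange_log`.
#' @export
read_exchange_log <- function(path, attempt_interval_steps = 500,
                              timestep_fs = 2, n_replicas = NULL) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t")
  exchange_log(rec, attempt_interval_steps, timestep_fs, n_replicas)
}

#' Exchange acceptance statistics
#'
#' @param log An `exchange_log`.
#' @return List with `per_pair` (data frame: `pair_lo`, `attempts`,
#'   `accepted`, `fraction`), `overall` acceptance fraction (the
#'   attempt-weighted mean of the per-pair rates) and
#'   `attempt_interval_ps`.
#' @export
acceptance_stats <- function(log) {
  stopifnot(inherits(log, "exchange_log"))
  rec <- log$records
  att <- tapply(rec$accepted, rec$pair_lo, length)
  acc <- tapply(rec$accepted, rec$pair_lo, sum)
  per_pair <- data.frame(pair_lo = as.integer(names(att)),
                         attempts = as.integer(att),
                         accepted = as.integer(acc),
                         fraction = as.numeric(acc / att))
  per_pair <- per_pair[order(per_pair$pair_lo), ]
  rownames(per_pair) <- NULL
  list(per_pair = per_pair,
       overall = sum(rec$accepted) / nrow(rec),
       attempt_interval_ps = log$attempt_interval_steps *
         log$timestep_fs / 1000)
}

#' Total-sampling bookkeeping for a replica-exchange protocol
#'
#' @param n_replicas Number of replicas.
#' @param ns_per_replica Simulated time per replica, ns.
#' @param metadata Optional named list of engine/protocol settings
#'   (force field, thermostat, cut-offs, ...) echoed verbatim into the
#'   report but never interpreted.
#' @return List with `n_replicas`, `ns_per_replica`, `combined_ns`,
#'   `combined_us` and `metadata`.
#' @examples
#' protocol_summary(10, 200)$combined_us  # 2 microseconds
#' @export
protocol_summary <- function(n_replicas, ns_per_replica, metadata = list()) {
  stopifnot(n_replicas >= 1, ns_per_replica > 0)
  combined <- n_replicas * ns_per_replica
  list(n_replicas = n_replicas, ns_per_replica = ns_per_replica,
       combined_ns = combined, combined_us = combined / 1000,
       metadata = metadata)
}
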