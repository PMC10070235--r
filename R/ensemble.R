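# Snapshot-ensemble statistics: per-label means and population variances
# over sets of trajectory frames, CT-gap and red-shift reports, and
# environment-minus-vacuum deltas. A synthetic ensemble generator emulates
# the frame-set statistics of the chlorophyll-dimer study conditions.

#' Snapshot table of per-frame quantities
#'
#' Long-format records of diabatic quantities per trajectory snapshot.
#' Keys `(snapshot, label, provenance)` must be unique and values finite.
#'
#' @param records data.frame with columns `snapshot`, `label`, `value_eV`
#'   and optionally `provenance` (`"vacuum"` or `"environment"`; default
#'   `"environment"`).
#' @param set_label name of the frame set (e.g. `"First50"`).
#' @return data.frame of class `snapshot_table` with attribute `set`.
#' @export
snapshot_table <- function(records, set_label = "set") {
  records <- as.data.frame(records)
  if (is.null(records$provenance)) records$provenance <- "environment"
  stopifnot(all(c("snapshot", "label", "value_eV") %in% names(records)))
  if (any(!is.finite(records$value_eV)))
    diabex_error("snapshot values must be finite", "input")
  key <- paste(records$snapshot, records$label, records$provenance)
  if (anyDuplicated(key))
    diabex_error("duplicate (snapshot, label, provenance) keys", "input")
  structure(records, set = set_label,
            class = c("snapshot_table", "data.frame"))
}

#' Per-label ensemble mean and population variance
#'
#' Population variance (divisor n) per label and provenance.
#'
#' @param table a [snapshot_table()].
#' @return data.frame with columns `label`, `provenance`, `n`, `mean`,
#'   `variance`, carrying the table's `set` attribute.
#' @export
ensemble_summary <- function(table) {
  agg <- stats::aggregate(value_eV ~ label + provenance, data = table,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              variance = mean((v - mean(v))^2)))
  out <- data.frame(label = agg$label, provenance = agg$provenance,
                    n = agg$value_eV[, "n"], mean = agg$value_eV[, "mean"],
                    variance = agg$value_eV[, "variance"])
  attr(out, "set") <- attr(table, "set")
  out
}

summary_mean <- function(summary, label, provenance = NULL) {
  rows <- summary$label == label
  if (!is.null(provenance)) rows <- rows & summary$provenance == provenance
  if (!any(rows))
    diabex_error(sprintf("label '%s' missing from ensemble summary", label),
                 "report")
  summary$mean[rows][1]
}

#' CT-gap and first-to-last shift report
#'
#' From two ensemble summaries (e.g. the first and last frame sets of a
#' trajectory) derives the absolute CT1-CT2 gap per set and the per-label
#' first-minus-last shifts (positive = red shift of the last set). Values
#' are kept at full precision; the print method rounds to 2 decimals.
#'
#' @param first,last [ensemble_summary()] results containing at least the
#'   labels `CT1`, `CT2` and `Qy2`.
#' @return object of class `gap_shift_report`: list with `ct_gap`
#'   (`c(first=, last=)`, eV) and `shift` (named vector of first-minus-last
#'   means for every label present in both summaries).
#' @export
gap_and_shift_report <- function(first, last) {
  for (s in list(first, last))
    if (!all(c("CT1", "CT2", "Qy2") %in% s$label))
      diabex_error("summaries must contain CT1, CT2 and Qy2", "report")
  gap <- c(first = abs(summary_mean(first, "CT2") -
                         summary_mean(first, "CT1")),
           last = abs(summary_mean(last, "CT2") -
                        summary_mean(last, "CT1")))
  common <- intersect(first$label, last$label)
  shift <- vapply(common, function(l)
    summary_mean(first, l) - summary_mean(last, l), numeric(1))
  structure(list(ct_gap = gap, shift = shift), class = "gap_shift_report")
}

#' @export
print.gap_shift_report <- function(x, ...) {
  cat("|dE_CT| (eV): first =", sprintf("%.2f", x$ct_gap["first"]),
      " last =", sprintf("%.2f", x$ct_gap["last"]), "\n")
  cat("first-minus-last shifts (eV):\n")
  print(round(x$shift, 2))
  invisible(x)
}

#' Record-wise environment-minus-vacuum differences
#'
#' Matches records by `(snapshot, label)` and returns
#' `value(environment) - value(vacuum)` per record. Unmatched snapshot ids
#' are listed in a warning and excluded.
#'
#' @param env_table,vac_table [snapshot_table()]s with matching snapshots.
#' @return data.frame with columns `snapshot`, `label`, `delta_eV`.
#' @export
env_delta <- function(env_table, vac_table) {
  key <- function(t) paste(t$snapshot, t$label, sep = "\r")
  ke <- key(env_table); kv <- key(vac_table)
  common <- intersect(ke, kv)
  missing <- union(setdiff(ke, kv), setdiff(kv, ke))
  if (length(missing))
    warning(sprintf("excluding %d unmatched record(s): %s",
                    length(missing),
                    paste(utils::head(gsub("\r", "/", missing), 5),
                          collapse = ", ")))
  ie <- match(common, ke); iv <- match(common, kv)
  data.frame(snapshot = env_table$snapshot[ie],
             label = env_table$label[ie],
             delta_eV = env_table$value_eV[ie] - vac_table$value_eV[iv])
}

#' Printed ensemble statistics of the chlorophyll-dimer study
#'
#' Frame-set averages and population variances of the diabatic energies
#' (Qy/Qx site energies, CT1/CT2) and of the absolute LE/LE and LE/CT
#' couplings for the two frame sets of the Chla611-Chla612 trajectory
#' (51 frames in the first set, 52 in the last), plus crystal-geometry
#' values. These table-level aggregates serve as worked-example inputs and
#' as the default study conditions of [simulate_dimer_ensemble()].
#'
#' @return data.frame with columns `label`, `kind` (`energy`/`coupling`),
#'   `mean_first`, `var_first`, `mean_last`, `var_last`, `crystal` (eV).
#' @export
chla_dimer_reference <- function() {
  data.frame(
    label = c("Qy1", "Qy2", "Qx1", "Qx2", "CT1", "CT2",
              "V_Qy", "V_Qx",
              "V_QyA_CT1", "V_QyA_CT2", "V_QxA_CT2",
              "V_QyB_CT1", "V_QyB_CT2", "V_QxB_CT1"),
    kind = rep(c("energy", "coupling"), c(6, 8)),
    mean_first = c(2.02, 2.01, 2.27, 2.26, 2.77, 3.28,
                   0.021, 0.009, 0.009, 0.019, 0.017, 0.019, 0.009, 0.015),
    var_first = c(0.001, 0.001, 0.001, 0.002, 0.008, 0.011,
                  6.2e-6, 2.8e-6, 4.3e-5, 1.8e-4, 2.2e-4,
                  1.9e-4, 4.5e-5, 9.1e-5),
    mean_last = c(2.03, 1.99, 2.28, 2.21, 2.59, 2.52,
                  0.029, 0.017, 0.014, 0.054, 0.062, 0.055, 0.014, 0.128),
    var_last = c(0.001, 0.001, 0.001, 0.002, 0.009, 0.012,
                 3.1e-5, 1.6e-5, 1.2e-4, 1.6e-3, 2.0e-3,
                 1.6e-3, 1.2e-4, 3.4e-3),
    crystal = c(2.07, 2.02, 2.36, 2.34, 2.83, 3.28,
                0.026, 0.005, 0.005, 0.019, 0.015, 0.020, 0.007, 0.014)
  )
}

#' Simulate a snapshot ensemble of diabatic quantities
#'
#' Draws per-snapshot values of the six diabatic energies and eight LE-CT /
#' LE-LE coupling magnitudes from independent normal distributions whose
#' means and population variances default to the frame-set statistics of
#' [chla_dimer_reference()] (51 frames for the first set, 52 for the last).
#' Coupling magnitudes are truncated at zero. The generator emulates
#' uncorrelated snapshot-to-snapshot fluctuation about the set averages;
#' it does not model the geometric origin of those fluctuations.
#'
#' @param set `"first"` or `"last"` frame-set conditions.
#' @param n number of snapshots; defaults to 51/52 per set.
#' @param reference statistics table in [chla_dimer_reference()] layout.
#' @param provenance provenance tag for the records.
#' @return a [snapshot_table()].
#' @export
simulate_dimer_ensemble <- function(set = c("first", "last"), n = NULL,
                                    reference = chla_dimer_reference(),
                                    provenance = "environment") {
  set <- match.arg(set)
  if (is.null(n)) n <- if (set == "first") 51L else 52L
  mu <- reference[[paste0("mean_", set)]]
  sd <- sqrt(reference[[paste0("var_", set)]])
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    v <- stats::rnorm(length(mu), mu, sd)
    v[reference$kind == "coupling"] <- pmax(v[reference$kind == "coupling"], 0)
    v[reference$kind == "energy"] <- pmax(v[reference$kind == "energy"], 1e-3)
    data.frame(snapshot = i, label = reference$label, value_eV = v,
               provenance = provenance)
  }))
  snapshot_table(rec, set_label = if (set == "first") "First50" else "Last50")
}

#' Assemble the model for one snapshot's values
#'
#' Maps one snapshot's labelled values (layout of [chla_dimer_reference()])
#' onto a [assemble_diabatic()] call with identity diabatic overlap and
#' positive coupling signs (the tabulated couplings are magnitudes).
#'
#' @param values named numeric vector of the 14 labelled quantities (eV).
#' @return a `diabatic_model`.
#' @export
snapshot_model <- function(values) {
  v <- as.list(values)
  lect <- rbind(QyA = c(v$V_QyA_CT1, v$V_QyA_CT2),
                QxA = c(0, v$V_QxA_CT2),
                QyB = c(v$V_QyB_CT1, v$V_QyB_CT2),
                QxB = c(v$V_QxB_CT1, 0))
  colnames(lect) <- c("CT1", "CT2")
  assemble_diabatic(
    site_energies(v$Qy1, v$Qx1, v$Qy2, v$Qx2, provenance = "file"),
    le_coupling = list(VQy = v$V_Qy, VQx = v$V_Qx),
    ct = c(CT1 = v$CT1, CT2 = v$CT2),
    lect = lect)
}

#' Assemble and solve the model for one snapshot's values
#'
#' @param values named numeric vector of the 14 labelled quantities (eV).
#' @return a [solve_diabatic()] solution.
#' @export
solve_snapshot <- function(values) {
  solve_diabatic(snapshot_model(values))
}

#' Lowest-state ensemble analysis of a snapshot table
#'
#' Solves the diabatic model for every snapshot of a table and returns the
#' lowest adiabatic energies.
#'
#' @param table a [snapshot_table()] with the 14 labels of
#'   [chla_dimer_reference()] per snapshot.
#' @return numeric vector of lowest adiabatic energies (eV), one per
#'   snapshot.
#' @export
ensemble_lowest_states <- function(table) {
  snaps <- unique(table$snapshot)
  vapply(snaps, function(s) {
    rows <- table$snapshot == s
    vals <- stats::setNames(table$value_eV[rows], table$label[rows])
    solve_snapshot(vals)$energies[1]
  }, numeric(1))
}
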