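#' Call QTL peaks on a LOD profile
#'
#' Each maximal contiguous run of scan positions with `LOD >= threshold`
#' (within one chromosome; runs on different chromosomes never merge)
#' yields one call at the run's maximum LOD, ties broken leftmost.
#'
#' @param profile a `qei_scan` data.frame (ordered by chromosome and
#'   position).
#' @param threshold LOD threshold for significance.
#' @return data.frame of peak rows from the profile (possibly 0 rows).
#' @export
call_peaks <- function(profile, threshold) {
  if (!nrow(profile)) return(profile)
  sig <- profile$LOD >= threshold
  out <- list()
  for (ch in unique(profile$chromosome)) {
    idx <- which(profile$chromosome == ch & sig)
    if (!length(idx)) next
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (run in runs) {
      best <- run[which.max(profile$LOD[run])]   # which.max -> leftmost tie
      out[[length(out) + 1L]] <- profile[best, , drop = FALSE]
    }
  }
  if (!length(out)) return(profile[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power, false discovery rate and estimate bias over replicates
#'
#' A replicate detects true QTL `j` when at least one call lies within
#' `support_halfwidth` cM of its true position on its chromosome (multiple
#' calls inside one support interval count as one detection).  Calls
#' outside every support interval are false positives; a call inside two
#' overlapping intervals is assigned to the nearest truth.  FDR pools all
#' replicates: `100 * false positives / all calls`.  Estimated positions
#' and effects are averaged over detecting calls only.
#'
#' @param calls_list list with one [call_peaks()] result per replicate.
#' @param truth a [qtl_architecture()] of the true QTL.
#' @param support_halfwidth half-width of the support interval in cM
#'   (default 5, i.e. a 10 cM interval).
#' @return list of class `power_report` with `per_qtl` (data.frame: power %,
#'   mean/SE of position, average effect and interaction effects), `FDR`
#'   (%), `n_replicates`, `n_calls`, `n_false`.
#' @export
power_fdr <- function(calls_list, truth, support_halfwidth = 5) {
  nq <- length(truth$chromosome)
  nrep <- length(calls_list)
  e <- ncol(truth$effects)
  detected <- matrix(FALSE, nrep, nq)
  est <- vector("list", nq)
  n_calls <- 0L
  n_false <- 0L
  for (b in seq_len(nrep)) {
    calls <- calls_list[[b]]
    if (is.null(calls) || !nrow(calls)) next
    n_calls <- n_calls + nrow(calls)
    for (ci in seq_len(nrow(calls))) {
      d <- ifelse(truth$chromosome == as.character(calls$chromosome[ci]),
                  abs(truth$position_cM - calls$position_cM[ci]), Inf)
      j <- which.min(d)
      if (nq && d[j] <= support_halfwidth) {
        detected[b, j] <- TRUE
        est[[j]][[length(est[[j]]) + 1L]] <- calls[ci, , drop = FALSE]
      } else {
        n_false <- n_false + 1L
      }
    }
  }
  per_qtl <- NULL
  if (nq) {
    mean_se <- function(x) c(mean = mean(x), se = stats::sd(x))
    rows <- lapply(seq_len(nq), function(j) {
      calls <- if (length(est[[j]])) do.call(rbind, est[[j]]) else NULL
      row <- data.frame(qtl = j, chromosome = truth$chromosome[j],
                        true_position = truth$position_cM[j],
                        power = 100 * mean(detected[, j]))
      stat_cols <- c("position_cM", "avg_effect",
                     paste0("ae_", seq_len(e)))
      for (cn in stat_cols) {
        v <- if (!is.null(calls)) calls[[cn]] else numeric(0)
        row[[paste0(cn, "_mean")]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0(cn, "_se")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      }
      row
    })
    per_qtl <- do.call(rbind, rows)
  }
  structure(list(per_qtl = per_qtl,
                 FDR = if (n_calls > 0) 100 * n_false / n_calls else NA_real_,
                 n_replicates = nrep, n_calls = n_calls, n_false = n_false),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("Power report over", x$n_replicates, "replicates:",
      x$n_calls, "calls,", x$n_false, "false positives (FDR =",
      format(x$FDR, digits = 4), "%)\n")
  if (!is.null(x$per_qtl))
    print(x$per_qtl[, c("qtl", "chromosome", "true_position", "power",
                        "position_cM_mean", "avg_effect_mean")], ...)
  invisible(x)
}

#' Detection frequency by marker interval
#'
#' Attributes each call to the marker interval containing its position (a
#' call exactly at a marker goes to the interval on its right, except at
#' the last marker of a chromosome) and reports the share of replicates
#' with at least one call in each interval.
#'
#' @param calls_list list with one [call_peaks()] result per replicate.
#' @param map the [genetic_map()].
#' @return data.frame with one row per marker interval: `chromosome`,
#'   `left_marker`, `right_marker`, `start_cM`, `end_cM`, `frequency` (%).
#' @export
interval_power <- function(calls_list, map) {
  chrs <- map_by_chromosome(map)
  iv <- do.call(rbind, lapply(names(chrs), function(ch) {
    d <- chrs[[ch]]
    m <- nrow(d)
    data.frame(chromosome = ch,
               left_marker = d$marker[-m], right_marker = d$marker[-1L],
               start_cM = d$position_cM[-m], end_cM = d$position_cM[-1L])
  }))
  hit <- matrix(FALSE, length(calls_list), nrow(iv))
  for (b in seq_along(calls_list)) {
    calls <- calls_list[[b]]
    if (is.null(calls) || !nrow(calls)) next
    for (ci in seq_len(nrow(calls))) {
      on_chr <- iv$chromosome == as.character(calls$chromosome[ci])
      p <- calls$position_cM[ci]
      inside <- on_chr & p >= iv$start_cM & p < iv$end_cM
      if (!any(inside))  # last marker of the chromosome
        inside <- on_chr & p >= iv$start_cM & p <= iv$end_cM
      w <- which(inside)
      if (length(w)) hit[b, w[1L]] <- TRUE
    }
  }
  iv$frequency <- 100 * colMeans(hit)
  iv
}
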