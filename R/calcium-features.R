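#' Analysis protocol windows for a three-phase calcium recording
#'
#' Windows are half-open on the right, \code{[start, end)}, in seconds from
#' the start of the recording. The resting level is read from the baseline
#' window (first 30 s by convention), the Ca2+ store content from the CPA /
#' Ca2+-free release window, and SOCE from the Ca2+ re-addition window.
#'
#' @param phase_times Numeric length 3: baseline end, Ca2+ re-addition time,
#'   recording end (seconds).
#' @param baseline_window Window for the resting level, default \code{c(0, 30)}.
#' @param baseline_span Seconds of signal immediately preceding a response
#'   window whose median serves as that window's baseline reference
#'   (default 15).
#' @return List of class \code{ca_protocol} with \code{baseline_window},
#'   \code{release_window}, \code{soce_window}, \code{baseline_span}.
#' @export
default_protocol <- function(phase_times = c(60, 360, 600),
                             baseline_window = c(0, 30),
                             baseline_span = 15) {
  if (length(phase_times) != 3 || any(diff(phase_times) <= 0))
    stop("phase_times must be three strictly increasing values")
  prot <- list(baseline_window = baseline_window,
               release_window = c(phase_times[1], phase_times[2]),
               soce_window = c(phase_times[2], phase_times[3]),
               baseline_span = baseline_span)
  class(prot) <- "ca_protocol"
  prot
}

#' Resting calcium level of a trace
#'
#' Median F340/F380 ratio over the baseline window (by default the first
#' 30 s of the recording). The median makes the estimate robust to isolated
#' artefacts in the baseline.
#'
#' @param times,ratios Equal-length numeric vectors, times in seconds
#'   strictly increasing.
#' @param protocol A [default_protocol()] (or any list with a
#'   \code{baseline_window}).
#' @return Resting ratio (scalar).
#' @export
resting_level <- function(times, ratios, protocol = default_protocol()) {
  w <- protocol$baseline_window
  sel <- times >= w[1] & times < w[2]
  if (sum(sel) < 2)
    stop("baseline window [", w[1], ", ", w[2], ") covers fewer than ",
         "2 samples")
  stats::median(ratios[sel])
}

#' Peak increment and area under the curve of a response window
#'
#' Both metrics are computed on the baseline-subtracted signal: \code{dmax}
#' is the maximum of \code{ratio - baseline_ref} over the window and
#' \code{auc} its trapezoidal integral (ratio x seconds). Negative
#' excursions are not clipped, so the AUC of a response that dips below its
#' local baseline can be negative. Sampling need not be uniform.
#'
#' @param times,ratios Equal-length numeric vectors, times strictly
#'   increasing.
#' @param window Numeric length 2, half-open \code{[start, end)} in seconds.
#' @param baseline_ref Reference level subtracted before measuring
#'   (typically the median of the signal just before the window).
#' @return Named numeric: \code{dmax} (ratio) and \code{auc} (ratio * s).
#' @export
response_metrics <- function(times, ratios, window, baseline_ref) {
  sel <- times >= window[1] & times < window[2]
  if (sum(sel) < 2)
    stop("window [", window[1], ", ", window[2],
         ") covers fewer than 2 samples of the recording")
  y <- ratios[sel] - baseline_ref
  t <- times[sel]
  c(dmax = max(y),
    auc = sum(diff(t) * (y[-length(y)] + y[-1]) / 2))
}

# Median of the baseline_span seconds immediately preceding window_start.
local_baseline <- function(times, ratios, window_start, baseline_span) {
  sel <- times >= window_start - baseline_span & times < window_start
  if (sum(sel) < 1) return(NA_real_)
  stats::median(ratios[sel])
}

#' Extract per-cell calcium features from a trace set
#'
#' For every cell, computes the resting level over the baseline window, the
#' Ca2+ store content metrics (\code{store_dmax}, \code{store_auc}) over the
#' CPA release window, and the SOCE metrics (\code{soce_dmax},
#' \code{soce_auc}) over the Ca2+ re-addition window. The baseline reference
#' of each response window is the median of the \code{baseline_span} seconds
#' immediately preceding it, which is robust to slow drift.
#'
#' Cells whose traces fail the preconditions (non-finite values,
#' non-increasing times, or any analysis window with fewer than two samples)
#' are skipped and listed in the rejects report; the run continues.
#'
#' @param traces Long data.frame with columns \code{cell_id}, \code{day},
#'   \code{coverslip}, \code{line}, \code{treatment}, \code{time_s},
#'   \code{ratio}.
#' @param protocol A [default_protocol()].
#' @return data.frame with one row per accepted cell: metadata columns plus
#'   \code{resting}, \code{store_dmax}, \code{store_auc}, \code{soce_dmax},
#'   \code{soce_auc}. The rejects report (data.frame \code{cell_id},
#'   \code{reason}) is attached as attribute \code{"rejects"}.
#' @export
#' @examples
#' sim <- simulate_calcium(calcium_sim_config(seed = 1))
#' feats <- extract_features(sim$traces, default_protocol())
#' head(feats)
extract_features <- function(traces, protocol = default_protocol()) {
  need <- c("cell_id", "day", "coverslip", "line", "treatment",
            "time_s", "ratio")
  if (!all(need %in% names(traces)))
    stop("traces must have columns ", paste(need, collapse = ", "))
  o <- order(traces$cell_id, traces$time_s)
  traces <- traces[o, , drop = FALSE]
  idx <- split(seq_len(nrow(traces)), traces$cell_id)

  feats <- vector("list", length(idx))
  rejects <- list()
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    tt <- traces$time_s[rows]
    yy <- traces$ratio[rows]
    id <- traces$cell_id[rows[1]]
    res <- tryCatch({
      if (any(!is.finite(yy)) || any(!is.finite(tt)))
        stop("non-finite values")
      if (any(diff(tt) <= 0))
        stop("times not strictly increasing")
      rest <- resting_level(tt, yy, protocol)
      ref_store <- local_baseline(tt, yy, protocol$release_window[1],
                                  protocol$baseline_span)
      ref_soce <- local_baseline(tt, yy, protocol$soce_window[1],
                                 protocol$baseline_span)
      if (is.na(ref_store) || is.na(ref_soce))
        stop("empty pre-window baseline")
      store <- response_metrics(tt, yy, protocol$release_window, ref_store)
      soce <- response_metrics(tt, yy, protocol$soce_window, ref_soce)
      data.frame(cell_id = id,
                 day = traces$day[rows[1]],
                 coverslip = traces$coverslip[rows[1]],
                 line = traces$line[rows[1]],
                 treatment = traces$treatment[rows[1]],
                 resting = rest,
                 store_dmax = store[["dmax"]],
                 store_auc = store[["auc"]],
                 soce_dmax = soce[["dmax"]],
                 soce_auc = soce[["auc"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(cell_id = id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      feats[[i]] <- res
    }
  }
  out <- do.call(rbind, feats[!vapply(feats, is.null, logical(1))])
  if (is.null(out))
    stop("no cell passed the extraction preconditions")
  rownames(out) <- NULL
  attr(out, "rejects") <- if (length(rejects))
    do.call(rbind, rejects)
  else
    data.frame(cell_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}
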