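#' Configuration for the single-cell calcium trace simulator
#'
#' Describes a four-condition (cell line x treatment) fura-2 imaging
#' experiment with the hierarchical structure of the real design: recordings
#' on several days, several coverslips per condition and day, and many cells
#' per coverslip. Traces follow a three-phase protocol: flat baseline in
#' Ca2+-containing medium, Ca2+ release induced by CPA in Ca2+-free medium
#' (transient pulse), and Ca2+ re-addition evoking store-operated Ca2+ entry
#' (saturating plateau).
#'
#' @param n_days Number of experimental days (default 4).
#' @param coverslips_per_condition_day Coverslips per condition per day
#'   (default 2, so 8 coverslips per condition in total).
#' @param cells_per_coverslip Mean number of cells per coverslip (default 33).
#' @param cells_jitter Half-width of the uniform integer jitter on the
#'   per-coverslip cell count (default 4), so per-condition totals land in
#'   the 230-300 range typical of these experiments.
#' @param sample_interval Sampling cadence in seconds (default 5).
#' @param phase_times Numeric length 3, strictly increasing: end of baseline,
#'   Ca2+ re-addition time, end of recording, in seconds
#'   (default \code{c(60, 360, 600)}).
#' @param condition_means data.frame with columns \code{line},
#'   \code{treatment}, \code{resting} (baseline F340/F380 ratio),
#'   \code{release} (CPA release amplitude, ratio units) and \code{soce}
#'   (SOCE plateau amplitude, ratio units). Defaults encode the qualitative
#'   phenotype: cancer cells (HT29) show higher resting Ca2+ and SOCE but a
#'   lower store content than normal cells (NCM460), and DFMO shifts HT29
#'   toward the normal phenotype while barely affecting NCM460.
#' @param variance_components Named numeric: \code{day}, \code{coverslip},
#'   \code{cell} (additive random-intercept SDs) and \code{noise}
#'   (per-sample measurement SD), all in ratio units.
#' @param kinetics Named numeric: \code{release_rise} and
#'   \code{release_decay} time constants of the CPA release pulse and
#'   \code{soce_tau} of the SOCE approach to plateau, in seconds.
#' @param seed Integer seed.
#' @return A list of class \code{calcium_sim_config}.
#' @export
calcium_sim_config <- function(n_days = 4L,
                               coverslips_per_condition_day = 2L,
                               cells_per_coverslip = 33L,
                               cells_jitter = 4L,
                               sample_interval = 5,
                               phase_times = c(60, 360, 600),
                               condition_means = NULL,
                               variance_components = c(day = 0.02,
                                                       coverslip = 0.02,
                                                       cell = 0.05,
                                                       noise = 0.02),
                               kinetics = c(release_rise = 10,
                                            release_decay = 45,
                                            soce_tau = 20),
                               seed = 1L) {
  if (is.null(condition_means)) {
    condition_means <- data.frame(
      line      = c("NCM460", "NCM460", "HT29", "HT29"),
      treatment = c("control", "DFMO", "control", "DFMO"),
      resting   = c(0.40, 0.38, 0.50, 0.42),
      release   = c(0.60, 0.55, 0.35, 0.55),
      soce      = c(0.45, 0.45, 0.80, 0.55),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_days = as.integer(n_days),
              coverslips_per_condition_day =
                as.integer(coverslips_per_condition_day),
              cells_per_coverslip = as.integer(cells_per_coverslip),
              cells_jitter = as.integer(cells_jitter),
              sample_interval = sample_interval,
              phase_times = phase_times,
              condition_means = condition_means,
              variance_components = variance_components,
              kinetics = kinetics,
              seed = as.integer(seed))
  validate_calcium_config(cfg)
  class(cfg) <- "calcium_sim_config"
  cfg
}

validate_calcium_config <- function(cfg) {
  if (length(cfg$phase_times) != 3 || any(diff(cfg$phase_times) <= 0))
    stop("phase_times must be three strictly increasing values ",
         "(baseline end, re-addition, recording end)")
  if (any(cfg$variance_components < 0))
    stop("variance components must be non-negative")
  vc <- c("day", "coverslip", "cell", "noise")
  if (!all(vc %in% names(cfg$variance_components)))
    stop("variance_components must name ", paste(vc, collapse = ", "))
  cm <- cfg$condition_means
  if (nrow(cm) != 4 ||
      nrow(unique(cm[, c("line", "treatment")])) != 4)
    stop("condition_means must define exactly four line x treatment ",
         "conditions")
  if (cfg$phase_times[1] <= cfg$sample_interval)
    stop("baseline phase must contain at least two samples")
  invisible(cfg)
}

#' Noiseless trace template for one condition
#'
#' Builds the deterministic part of a trace on the sampled time grid:
#' zero baseline, a difference-of-exponentials release pulse scaled so its
#' sampled maximum inside the release window equals \code{release}, and a
#' saturating SOCE term scaled so its sampled maximum inside the SOCE window
#' equals \code{soce}. The resting level is added on top by the simulator.
#'
#' @param times Sampled time grid (seconds).
#' @param phase_times As in [calcium_sim_config()].
#' @param release,soce Amplitudes in ratio units.
#' @param kinetics Named numeric as in [calcium_sim_config()].
#' @return Numeric vector of template values (ratio units, baseline 0).
#' @export
trace_template <- function(times, phase_times, release, soce, kinetics) {
  t_b <- phase_times[1]; t_r <- phase_times[2]; t_end <- phase_times[3]
  tau_r <- kinetics[["release_rise"]]
  tau_d <- kinetics[["release_decay"]]
  tau_s <- kinetics[["soce_tau"]]
  y <- numeric(length(times))
  rel <- times >= t_b
  pulse <- exp(-(times[rel] - t_b) / tau_d) - exp(-(times[rel] - t_b) / tau_r)
  in_rel_win <- times >= t_b & times < t_r
  peak <- max(exp(-(times[in_rel_win] - t_b) / tau_d) -
                exp(-(times[in_rel_win] - t_b) / tau_r))
  y[rel] <- y[rel] + release * pulse / peak
  soce_on <- times >= t_r
  rise <- 1 - exp(-(times[soce_on] - t_r) / tau_s)
  in_soce_win <- times >= t_r & times < t_end
  top <- max(1 - exp(-(times[in_soce_win] - t_r) / tau_s))
  y[soce_on] <- y[soce_on] + soce * rise / top
  y
}

#' Simulate a single-cell calcium imaging experiment
#'
#' Generates one F340/F380 ratio trace per cell as
#' resting + day intercept + coverslip intercept + cell intercept +
#' phase template + Gaussian noise, under the hierarchical design of
#' [calcium_sim_config()]. Day intercepts are shared by all conditions run
#' on that day; coverslip intercepts are nested within day x condition.
#'
#' @param config A [calcium_sim_config()].
#' @return List with elements \code{traces} (long data.frame with columns
#'   \code{cell_id}, \code{day}, \code{coverslip}, \code{line},
#'   \code{treatment}, \code{time_s}, \code{ratio}) and \code{truth}
#'   (data.frame of per-condition true feature values, obtained by running
#'   the feature extractor on the noiseless template; see
#'   [extract_features()]).
#' @export
#' @examples
#' sim <- simulate_calcium(calcium_sim_config(seed = 7))
#' table(sim$traces$line, sim$traces$treatment) / length(unique(sim$traces$time_s))
simulate_calcium <- function(config) {
  validate_calcium_config(config)
  set.seed(config$seed)
  times <- seq(0, config$phase_times[3], by = config$sample_interval)
  nt <- length(times)
  vc <- config$variance_components
  cm <- config$condition_means
  cm$condition <- paste(cm$line, cm$treatment, sep = ".")

  day_eff <- stats::rnorm(config$n_days, 0, vc[["day"]])
  out <- vector("list", nrow(cm) * config$n_days *
                  config$coverslips_per_condition_day)
  k <- 0L
  cell_counter <- 0L
  for (d in seq_len(config$n_days)) {
    for (ci in seq_len(nrow(cm))) {
      template <- trace_template(times, config$phase_times,
                                 cm$release[ci], cm$soce[ci],
                                 config$kinetics)
      for (cs in seq_len(config$coverslips_per_condition_day)) {
        cov_eff <- stats::rnorm(1, 0, vc[["coverslip"]])
        n_cells <- config$cells_per_coverslip
        if (config$cells_jitter > 0)
          n_cells <- n_cells + sample.int(2L * config$cells_jitter + 1L,
                                          1L) - config$cells_jitter - 1L
        cell_eff <- stats::rnorm(n_cells, 0, vc[["cell"]])
        noise <- matrix(stats::rnorm(n_cells * nt, 0, vc[["noise"]]),
                        nrow = nt)
        ratio <- cm$resting[ci] + day_eff[d] + cov_eff +
          rep(cell_eff, each = nt) + rep(template, n_cells) + as.vector(noise)
        ids <- sprintf("cell%05d", cell_counter + seq_len(n_cells))
        cell_counter <- cell_counter + n_cells
        k <- k + 1L
        out[[k]] <- data.frame(
          cell_id = rep(ids, each = nt),
          day = sprintf("d%d", d),
          coverslip = sprintf("c%d", cs),
          line = cm$line[ci],
          treatment = cm$treatment[ci],
          time_s = rep(times, n_cells),
          ratio = ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  traces <- do.call(rbind, out)
  rownames(traces) <- NULL
  truth <- calcium_truth(config)
  list(traces = traces, truth = truth)
}

# True per-condition feature values: features of the noiseless template.
calcium_truth <- function(config) {
  times <- seq(0, config$phase_times[3], by = config$sample_interval)
  cm <- config$condition_means
  prot <- default_protocol(config$phase_times)
  rows <- lapply(seq_len(nrow(cm)), function(ci) {
    y <- cm$resting[ci] + trace_template(times, config$phase_times,
                                         cm$release[ci], cm$soce[ci],
                                         config$kinetics)
    tr <- data.frame(cell_id = "template", day = "d0", coverslip = "c0",
                     line = cm$line[ci], treatment = cm$treatment[ci],
                     time_s = times, ratio = y, stringsAsFactors = FALSE)
    extract_features(tr, prot)
  })
  truth <- do.call(rbind, rows)
  truth$cell_id <- NULL
  truth$day <- NULL
  truth$coverslip <- NULL
  cbind(truth[, c("line", "treatment")],
        truth[, setdiff(names(truth), c("line", "treatment"))])
}
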