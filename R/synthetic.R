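# Seeded synthetic cohorts of parent scans.
#
# The generator emulates exactly the three statistical structures the
# pipeline's distances detect, at desk scale:
#   (a) subject-specific per-region mean offsets, nearly constant across a
#       subject's task blocks (what raw Frobenius distance keys on);
#   (b) subject-specific inter-region correlation structure (what the Bures
#       distance on connectomes keys on);
#   (c) task-specific spatial activation patterns with a smooth temporal
#       waveform, shared across subjects (what survives de-meaning +
#       whitening and drives dM task clustering).
# It makes no claim of hemodynamic or physiological realism beyond these.

#' Configuration for a synthetic cohort
#'
#' Defaults are desk-scale (30 regions, 20 subjects, 8 tasks of 40 time
#' points) so that a full pipeline run takes seconds; the nominal
#' application scale is 268 regions and hundreds of subjects. Magnitudes
#' (arbitrary BOLD units): per-region baselines near `baseline_mean`;
#' between-subject mean offsets with spread `subject_mean_scale` (default
#' 10, i.e. 10% of baseline — within-subject, between-task mean differences
#' then arise from noise alone and are ~100x smaller); task patterns are
#' unit-norm spatial loadings scaled by `task_signal_strength` (default 5,
#' about a 1% peak per-region signal change); `noise_sd` (default 0.5) is
#' i.i.d. measurement noise on top of the unit-scale correlated neural
#' fluctuation.
#'
#' @param n_subjects number of subjects (default 20).
#' @param n_tasks number of task blocks per parent scan (default 8).
#' @param m_regions number of parcellated regions (default 30).
#' @param timepoints_per_task block length L (default 40); the total
#'   `n_tasks * timepoints_per_task` must exceed `m_regions` or whitening is
#'   singular.
#' @param subject_mean_scale spread of per-subject per-region mean offsets.
#' @param subject_cov_strength mixing weight `w` in `[0, 1)` of the
#'   subject-specific correlation factor.
#' @param task_signal_strength amplitude of the task-specific spatial
#'   pattern.
#' @param noise_sd standard deviation of i.i.d. sensor noise.
#' @param baseline_mean shared baseline BOLD level.
#' @param seed master seed; everything downstream is a deterministic
#'   function of it.
#' @param session `"test"` or `"retest"`. Retest scans contain the same
#'   task blocks in a fixed permuted order with fresh noise draws; subject
#'   profiles and task patterns are session-independent.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L, n_tasks = 8L, m_regions = 30L,
                          timepoints_per_task = 40L,
                          subject_mean_scale = 10,
                          subject_cov_strength = 0.6,
                          task_signal_strength = 5,
                          noise_sd = 0.5,
                          baseline_mean = 100,
                          seed = 0L,
                          session = c("test", "retest")) {
  session <- match.arg(session)
  if (n_tasks < 2) abort("n_tasks must be >= 2")
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (m_regions < 2) abort("m_regions must be >= 2")
  if (timepoints_per_task < 2) abort("timepoints_per_task must be >= 2")
  if (subject_mean_scale < 0 || task_signal_strength < 0 || noise_sd < 0) {
    abort("all strengths must be >= 0")
  }
  if (subject_cov_strength < 0 || subject_cov_strength >= 1) {
    abort("subject_cov_strength must be in [0, 1)")
  }
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        n_tasks = as.integer(n_tasks),
                        m_regions = as.integer(m_regions),
                        timepoints_per_task = as.integer(timepoints_per_task),
                        subject_mean_scale = subject_mean_scale,
                        subject_cov_strength = subject_cov_strength,
                        task_signal_strength = task_signal_strength,
                        noise_sd = noise_sd,
                        baseline_mean = baseline_mean,
                        seed = as.integer(seed),
                        session = session),
                   class = "cohort_config")
  n_total <- cfg$n_tasks * cfg$timepoints_per_task
  if (n_total <= cfg$m_regions) {
    abort(paste("total time points (%d) must exceed m_regions (%d) or",
                "whitening will be singular; increase timepoints_per_task"),
          n_total, cfg$m_regions)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d subjects x %d tasks, %d regions, ",
                     "%d tp/task, session '%s', seed %d\n"),
              x$n_subjects, x$n_tasks, x$m_regions, x$timepoints_per_task,
              x$session, x$seed))
  invisible(x)
}

# The 8 HCP working-memory conditions in their test-session order, and the
# retest-session order of the same conditions.
hcp_task_labels <- c("2bk-body", "0bk-face", "2bk-tool", "0bk-body",
                     "0bk-place", "2bk-face", "0bk-tool", "2bk-place")
hcp_retest_order <- c(3L, 4L, 6L, 7L, 1L, 8L, 2L, 5L)

task_labels_for <- function(config) {
  if (config$n_tasks == 8) hcp_task_labels
  else sprintf("task%02d", seq_len(config$n_tasks))
}

task_order_for <- function(config) {
  if (config$session == "test") return(seq_len(config$n_tasks))
  if (config$n_tasks == 8) return(hcp_retest_order)
  with_seed(derive_seed(config$seed, "retest-order"),
            sample.int(config$n_tasks))
}

random_orthogonal <- function(m) {
  qr_ <- qr(matrix(stats::rnorm(m * m), m, m))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), m)   # fix signs for a unique Q
}

#' Subject profile: mean offsets and correlation factor
#'
#' Draws the subject's per-region mean vector (baseline plus a
#' `subject_mean_scale`-spread offset, constant across the subject's task
#' blocks) and the SPD correlation-shaping factor
#' `C_s = (1 - w) I + w Q_s Lambda Q_s'` with `w = subject_cov_strength`,
#' `Q_s` a seeded random orthogonal matrix and `Lambda` a trace-normalized
#' geometric (spiked, ratio 0.8) spectrum, giving a few strong,
#' subject-specific correlation modes. Deterministic in
#' `(seed, subject_index)` and independent of the session.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return list with `mean_offsets` (length m), `correlation_factor`
#'   (m x m SPD), and its symmetric square root `sqrt_factor`.
#' @export
generate_subject_profile <- function(config, subject_index) {
  m <- config$m_regions
  with_seed(derive_seed(config$seed, "profile", subject_index), {
    mean_offsets <- config$baseline_mean +
      stats::rnorm(m, sd = config$subject_mean_scale)
    w <- config$subject_cov_strength
    if (w == 0) {
      C <- diag(1, m)
    } else {
      Q <- random_orthogonal(m)
      lam <- 0.8^(seq_len(m) - 1)
      lam <- lam * m / sum(lam)
      C <- sym((1 - w) * diag(1, m) + w * Q %*% (t(Q) * lam))
    }
    list(mean_offsets = mean_offsets,
         correlation_factor = C,
         sqrt_factor = psd_sqrt(C))
  })
}

#' Task-specific spatial activation patterns
#'
#' Unit-norm spatial loading vectors, one per task, mutually orthogonal
#' (random Gaussian draws orthonormalized by QR) and shared by all subjects
#' and sessions.
#'
#' @param config a [cohort_config()].
#' @param task_index 1-based task index (in the canonical test-session task
#'   enumeration, not block position).
#' @return numeric vector of length `m_regions` with unit norm.
#' @export
generate_task_pattern <- function(config, task_index) {
  m <- config$m_regions
  if (config$n_tasks > m) abort("cannot orthogonalize %d task patterns in %d regions",
                                config$n_tasks, m)
  if (task_index < 1 || task_index > config$n_tasks) abort("task_index out of range")
  P <- with_seed(derive_seed(config$seed, "patterns"), {
    qr.Q(qr(matrix(stats::rnorm(m * config$n_tasks), m, config$n_tasks)))
  })
  P[, task_index]
}

# smooth raised-cosine activation bump spanning a task block, in [0, 1]
activation_waveform <- function(L) {
  0.5 * (1 - cos(2 * pi * (seq_len(L) - 0.5) / L))
}

#' Generate one synthetic parent scan
#'
#' Concatenates `n_tasks` blocks of `timepoints_per_task` columns. Each
#' block is `mean_offsets + sqrt(C_s) z + strength * pattern_t * s(t) +
#' noise_sd * eps` with `z`, `eps` i.i.d. standard normal and `s(t)` the
#' raised-cosine activation waveform. Test sessions lay blocks down in
#' canonical task order; retest sessions use the fixed permuted order with
#' fresh noise. The annotation records each block's half-open interval and
#' task label.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return a [parent_scan()].
#' @export
generate_parent_scan <- function(config, subject_index) {
  m <- config$m_regions
  L <- config$timepoints_per_task
  profile <- generate_subject_profile(config, subject_index)
  labels <- task_labels_for(config)
  order_ <- task_order_for(config)
  s_t <- activation_waveform(L)
  blocks <- vector("list", config$n_tasks)
  for (pos in seq_along(order_)) {
    t_idx <- order_[pos]
    pattern <- generate_task_pattern(config, t_idx)
    noise <- with_seed(derive_seed(config$seed, config$session,
                                   subject_index, t_idx), {
      list(z = matrix(stats::rnorm(m * L), m, L),
           eps = matrix(stats::rnorm(m * L), m, L))
    })
    blocks[[pos]] <- profile$mean_offsets +
      profile$sqrt_factor %*% noise$z +
      config$task_signal_strength * outer(pattern, s_t) +
      config$noise_sd * noise$eps
  }
  starts <- (seq_len(config$n_tasks) - 1L) * L
  ann <- task_annotation(starts, starts + L, labels[order_])
  parent_scan(do.call(cbind, blocks), sprintf("sub-%03d", subject_index),
              ann, config$session)
}

#' Generate a full synthetic cohort
#'
#' One parent scan per subject plus the ground-truth label table (one row
#' per task interval). Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: list with `scans` (list of
#'   [parent_scan()]), `labels` (data.frame with `scan_id`, `subject`,
#'   `interval`, `task`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("config must be a cohort_config")
  scans <- lapply(seq_len(config$n_subjects), function(s) {
    generate_parent_scan(config, s)
  })
  labels <- do.call(rbind, lapply(scans, function(ps) {
    data.frame(scan_id = paste0(ps$subject_id, ":", ps$session_id),
               subject = ps$subject_id,
               interval = seq_len(nrow(ps$annotation)),
               task = ps$annotation$label,
               stringsAsFactors = FALSE)
  }))
  structure(list(scans = scans, labels = labels, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d tasks (%s session, seed %d)\n",
              x$config$n_subjects, x$config$n_tasks, x$config$session,
              x$config$seed))
  invisible(x)
}
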