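# Synthetic cohort generator: stable VAR(1) processes over the Yeo-7 channels
# with group-specific directed coupling templates, per-subject coupling
# jitter, and clinical scores linearly coupled to designated edges.

# Qualitative directed edge sets for the four built-in group templates,
# written as source -> target pairs over the Yeo-7 labels. They mirror the
# stage-specific patterns the analysis is designed to detect: young controls
# keep bidirectional control<->somatomotor coupling and top-down default-mode
# input to control; older groups replace it with attention->control and
# limbic->somatomotor routes; the prodromal stage isolates the somatomotor
# network (no outgoing edges); the manifest stage adds somatomotor reliance
# on visual and default-mode targets.
template_edge_sets <- function() {
  list(
    young_hc = list(c("FPN", "SMN"), c("SMN", "FPN"), c("DMN", "FPN"),
                    c("DAN", "LIN"), c("VAN", "LIN")),
    old_hc = list(c("DAN", "FPN"), c("VAN", "FPN"), c("VAN", "SMN"),
                  c("LIN", "SMN"), c("FPN", "DMN")),
    prodromal_pd = list(c("DAN", "FPN"), c("VAN", "FPN"), c("DAN", "SMN"),
                        c("VAN", "SMN"), c("FPN", "DAN"), c("FPN", "DMN"),
                        c("LIN", "SMN")),
    manifest_pd = list(c("DAN", "FPN"), c("VAN", "FPN"), c("DAN", "SMN"),
                       c("VAN", "SMN"), c("FPN", "DAN"), c("FPN", "DMN"),
                       c("LIN", "SMN"), c("SMN", "VIS"), c("SMN", "DMN"))
  )
}

#' Build a directed coupling template for a cohort group
#'
#' Returns the lag-1 coupling matrix of a stable VAR(1) generator: diagonal
#' entries equal `self_coupling`, off-diagonal entries equal `base_coupling`
#' exactly at the group's directed edges (source column -> target row) and 0
#' elsewhere. Built-in groups (`young_hc`, `old_hc`, `prodromal_pd`,
#' `manifest_pd`) carry distinct, documented edge sets; `custom` takes an
#' explicit edge list.
#'
#' @param name Group label: `"young_hc"`, `"old_hc"`, `"prodromal_pd"`,
#'   `"manifest_pd"` or `"custom"`.
#' @param base_coupling Off-diagonal coupling strength placed on each edge.
#' @param self_coupling Diagonal (within-channel) lag-1 coupling.
#' @param edges For `"custom"`: list of `c(source, target)` channel-name pairs
#'   (possibly empty).
#' @param channels Channel names; defaults to [yeo7_channels()].
#' @return An object of class `"coupling_template"` with fields `name`,
#'   `coupling` (N x N matrix), `self_coupling`, `edge_list`, `channels`.
#' @export
#' @examples
#' tpl <- make_template("young_hc", 0.3, 0.5)
#' tpl$edge_list
make_template <- function(name, base_coupling = 0.3, self_coupling = 0.5,
                          edges = NULL, channels = yeo7_channels()) {
  assert_scalar_num(base_coupling, "base_coupling")
  assert_scalar_num(self_coupling, "self_coupling")
  known <- template_edge_sets()
  if (name %in% names(known)) {
    edges <- known[[name]]
  } else if (identical(name, "custom")) {
    if (is.null(edges)) stop("custom template requires an explicit edge list",
                             call. = FALSE)
  } else {
    stop(sprintf("unknown group label '%s' (and no custom edges supplied)", name),
         call. = FALSE)
  }
  N <- length(channels)
  A <- diag(self_coupling, N)
  dimnames(A) <- list(channels, channels)
  for (e in edges) {
    if (!all(e %in% channels))
      stop(sprintf("edge (%s -> %s) uses unknown channel names", e[1], e[2]),
           call. = FALSE)
    A[e[2], e[1]] <- base_coupling
  }
  tpl <- structure(list(name = name, coupling = A, self_coupling = self_coupling,
                        edge_list = edges, channels = as.character(channels)),
                   class = "coupling_template")
  if (spectral_radius(A) >= 1)
    stop(sprintf("template '%s' is unstable (spectral radius %.3f >= 1)",
                 name, spectral_radius(A)), call. = FALSE)
  tpl
}

#' @export
print.coupling_template <- function(x, ...) {
  cat(sprintf("<coupling_template> '%s': %d channels, %d directed edges, self-coupling %g\n",
              x$name, length(x$channels), length(x$edge_list), x$self_coupling))
  for (e in x$edge_list)
    cat(sprintf("  %s -> %s : %g\n", e[1], e[2], x$coupling[e[2], e[1]]))
  invisible(x)
}

# Edge matrix (logical N x N, TRUE at (target, source)) from a template.
edge_mask <- function(tpl) {
  m <- matrix(FALSE, length(tpl$channels), length(tpl$channels),
              dimnames = dimnames(tpl$coupling))
  for (e in tpl$edge_list) m[e[2], e[1]] <- TRUE
  m
}

#' Simulate one subject's BOLD-like time series from a coupling template
#'
#' Runs the VAR(1) recursion `x(t) = A x(t-1) + e(t)` forward with i.i.d.
#' Gaussian innovations, discards the first 50 burn-in samples, and optionally
#' adds Gaussian observation noise. Deterministic given `seed`.
#'
#' @param template A [make_template()] object (or any stable
#'   `coupling_template`).
#' @param T_len Number of returned time points (>= 50).
#' @param TR Repetition time in seconds.
#' @param innovation_sd Innovation (process noise) standard deviation (> 0).
#' @param observation_noise_sd Additive measurement-noise SD (>= 0).
#' @param seed RNG seed.
#' @param subject_id Subject identifier.
#' @return A [time_series_set()] with `group` set to the template name.
#' @export
simulate_subject <- function(template, T_len = 400, TR = 2.0,
                             innovation_sd = 1.0, observation_noise_sd = 0.0,
                             seed = 1, subject_id = "subject") {
  stopifnot(inherits(template, "coupling_template"))
  if (T_len < 50) stop("T_len must be at least 50", call. = FALSE)
  assert_scalar_num(innovation_sd, "innovation_sd", positive = TRUE)
  assert_scalar_num(observation_noise_sd, "observation_noise_sd")
  if (observation_noise_sd < 0) stop("observation_noise_sd must be >= 0", call. = FALSE)
  A <- template$coupling
  if (spectral_radius(A) >= 1)
    stop("unstable template: spectral radius >= 1", call. = FALSE)
  N <- ncol(A)
  burn <- 50
  with_seed(seed, {
    x <- matrix(0, T_len + burn, N)
    prev <- rnorm(N, sd = innovation_sd)
    for (t in seq_len(T_len + burn)) {
      prev <- drop(A %*% prev) + rnorm(N, sd = innovation_sd)
      x[t, ] <- prev
    }
    x <- x[-seq_len(burn), , drop = FALSE]
    if (observation_noise_sd > 0)
      x <- x + matrix(rnorm(length(x), sd = observation_noise_sd), nrow(x), ncol(x))
    time_series_set(x, TR = TR, channels = template$channels,
                    subject_id = subject_id, group = template$name)
  })
}

#' Define a synthetic-cohort recipe
#'
#' @param groups List of `list(template = <coupling_template>, n = <count>)`
#'   entries.
#' @param T_len Time points per subject (>= 50).
#' @param TR Repetition time in seconds.
#' @param coupling_jitter_sd SD of the Gaussian perturbation applied to each
#'   nonzero off-diagonal coupling, independently per subject.
#' @param innovation_sd VAR innovation SD.
#' @param observation_noise_sd Additive measurement-noise SD.
#' @param clinical_model List of `list(edge = c(source, target), score =
#'   <name>, slope = <scalar>, noise_sd = <scalar>)`: each subject's score is
#'   `slope * (their true coupling on the edge) + N(0, noise_sd)`.
#' @param seed Cohort RNG seed; all per-subject seeds derive from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups, T_len = 400, TR = 2.0, coupling_jitter_sd = 0.05,
                        innovation_sd = 1.0, observation_noise_sd = 0.0,
                        clinical_model = list(), seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 1)
  for (g in groups) {
    stopifnot(inherits(g$template, "coupling_template"), g$n >= 1)
  }
  if (T_len < 50) stop("T_len must be at least 50", call. = FALSE)
  assert_scalar_num(TR, "TR", positive = TRUE)
  structure(list(groups = groups, T_len = T_len, TR = TR,
                 coupling_jitter_sd = coupling_jitter_sd,
                 innovation_sd = innovation_sd,
                 observation_noise_sd = observation_noise_sd,
                 clinical_model = clinical_model, seed = seed),
            class = "cohort_spec")
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Subjects are generated independently. Each subject's coupling matrix is
#' the group template with Gaussian jitter on the nonzero off-diagonal
#' couplings, rejection-sampled to stability (at most 100 retries). Clinical
#' scores are linear in the subject's true coupling on designated edges plus
#' Gaussian noise. Full provenance (per-subject seed and truth matrix) is
#' stored.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `"synthetic_cohort"` with fields `subjects`
#'   (list of `ts_set`), `truth` (per-subject coupling matrices and group
#'   edge lists), `clinical_scores` (data.frame) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  truth <- list()
  score_rows <- list()
  with_seed(spec$seed, {
    idx <- 0
    for (g in spec$groups) {
      tpl <- g$template
      mask <- edge_mask(tpl)
      for (k in seq_len(g$n)) {
        idx <- idx + 1
        sid <- sprintf("%s_%03d", tpl$name, k)
        A <- tpl$coupling
        ok <- FALSE
        for (try in seq_len(100)) {
          Aj <- A
          if (any(mask) && spec$coupling_jitter_sd > 0)
            Aj[mask] <- A[mask] + rnorm(sum(mask), sd = spec$coupling_jitter_sd)
          if (spectral_radius(Aj) < 1) { ok <- TRUE; break }
        }
        if (!ok) stop(sprintf("no stable jittered coupling for subject %s after 100 retries", sid),
                      call. = FALSE)
        sub_seed <- sample.int(.Machine$integer.max - 1L, 1)
        tpl_j <- tpl
        tpl_j$coupling <- Aj
        subj <- simulate_subject(tpl_j, T_len = spec$T_len, TR = spec$TR,
                                 innovation_sd = spec$innovation_sd,
                                 observation_noise_sd = spec$observation_noise_sd,
                                 seed = sub_seed, subject_id = sid)
        scores <- list(subject_id = sid, group = tpl$name)
        for (cm in spec$clinical_model) {
          val <- Aj[cm$edge[2], cm$edge[1]]
          scores[[cm$score]] <- cm$slope * val +
            (if (cm$noise_sd > 0) rnorm(1, sd = cm$noise_sd) else 0)
        }
        subjects[[idx]] <- subj
        truth[[idx]] <- list(subject_id = sid, group = tpl$name,
                             coupling = Aj, edge_list = tpl$edge_list,
                             seed = sub_seed)
        score_rows[[idx]] <- scores
      }
    }
  })
  clinical <- do.call(rbind, lapply(score_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(subjects = subjects, truth = truth,
                 clinical_scores = clinical, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat(sprintf("<synthetic_cohort> %d subjects (T = %d, TR = %g s)\n",
              length(x$subjects), x$spec$T_len, x$spec$TR))
  for (g in names(groups)) cat(sprintf("  %s: %d\n", g, groups[[g]]))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' One TSV per subject (header of channel names, one row per time point) plus
#' a sidecar JSON carrying the group label, TR, generator seed, true directed
#' edges and clinical scores.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    tr <- cohort$truth[[i]]
    write_timeseries(s, file.path(dir, paste0(s$subject_id, ".tsv")))
    scores <- cohort$clinical_scores[i, setdiff(names(cohort$clinical_scores),
                                                c("subject_id", "group")), drop = FALSE]
    side <- list(subject_id = s$subject_id, group = s$group, TR = s$TR,
                 seed = tr$seed,
                 truth_edges = lapply(tr$edge_list, function(e)
                   list(source = e[1], target = e[2],
                        coupling = tr$coupling[e[2], e[1]])),
                 clinical_scores = as.list(scores))
    jsonlite::write_json(side, file.path(dir, paste0(s$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
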