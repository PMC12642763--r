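# End-to-end convenience: cohort -> pairwise distances -> Isomap -> k-means
# -> ARS/AMI score table.

#' Run the full distance / embedding / clustering pipeline on a cohort
#'
#' For `metric = "frobenius_raw"` and `"bures_connectome"` the task scans
#' are extracted from the raw parent scans; for `"dM"` the parents are
#' de-meaned and whitened first (once per parent) and task scans are
#' extracted from the whitened matrices. The resulting pairwise distance
#' matrix is embedded with Isomap and the embedding is scored against the
#' cohort's subject and task labels with k-means + AMI/ARS.
#'
#' @param cohort a [generate_cohort()] result, or a list of
#'   [parent_scan()]s plus a matching `labels` data.frame.
#' @param metric distance route (see [pairwise_distances()]).
#' @param k Isomap neighbourhood size (default 10).
#' @param d embedding dimension used for clustering (default 20).
#' @param seed seed for k-means.
#' @param ridge whitening ridge (dM only).
#' @param n_restarts k-means restarts.
#' @return list with `distances` (the [distance_matrix()]), `embedding`
#'   (the `embedding_result`), and `scores` (2 x 2 data.frame, rows AMI/ARS,
#'   columns task/subject).
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_config(n_subjects = 4, n_tasks = 3,
#'                                     m_regions = 10, seed = 1))
#' run_pipeline(co, "frobenius_raw", k = 5, d = 5)$scores
#' }
#' @export
run_pipeline <- function(cohort,
                         metric = c("frobenius_raw", "bures_connectome", "dM"),
                         k = 10, d = 20, seed = 0L, ridge = 0,
                         n_restarts = 10L) {
  metric <- match.arg(metric)
  if (!inherits(cohort, "cohort")) abort("cohort must be a generate_cohort() result")
  objects <- if (metric == "dM") cohort$scans
             else unlist(lapply(cohort$scans, extract_task_scans), recursive = FALSE)
  D <- pairwise_distances(objects, metric = metric, ridge = ridge)
  emb <- embed_distances(D, k = k, d = d, backend = "isomap")
  scores <- evaluate_embedding(emb, cohort$labels$subject, cohort$labels$task,
                               seed = seed, n_restarts = n_restarts)
  list(distances = D, embedding = emb, scores = scores)
}
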