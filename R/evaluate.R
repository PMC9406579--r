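# Held-out evaluation of a trained model against a dataset manifest.

#' Evaluate a trained model on a manifest
#'
#' Runs prediction for every requested sample and scores it with the full
#' metric set ([evaluate_case()]) at the network resolution: the ground-truth
#' mask is resized (nearest-neighbour) to the network grid and compared with
#' the probability map, so average Hausdorff distances are in network-grid
#' pixels. By default the model's own recorded validation ids are evaluated,
#' and any overlap between the evaluated ids and the recorded training ids
#' raises a leakage error.
#'
#' @param model A trained `rda_model`.
#' @param manifest Manifest tibble or path.
#' @param threshold Binarization threshold.
#' @param ids Sample ids to evaluate; defaults to the model's validation ids.
#' @param allow_overlap Set `TRUE` to evaluate ids seen in training
#'   (explicit override of the leakage check).
#' @param out_dir Optional directory; writes `cases.tsv` (per-case metrics)
#'   and `aggregate.json`.
#' @return List with `cases` (per-case tibble, one row per sample) and
#'   `aggregate` (one-row tibble from [aggregate_metrics()]).
#' @export
evaluate_run <- function(model, manifest, threshold = 0.5, ids = NULL,
                         allow_overlap = FALSE, out_dir = NULL) {
  stopifnot(inherits(model, "rda_model"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(ids)) ids <- intersect(model$split$val_ids, manifest$sample_id)
  if (length(ids) == 0) stop("no ids to evaluate", call. = FALSE)
  leaked <- intersect(ids, model$split$train_ids)
  if (length(leaked) > 0 && !allow_overlap) {
    stop(sprintf("evaluation ids overlap the recorded training set (%s%s); use allow_overlap = TRUE to override",
                 paste(head(leaked, 3), collapse = ", "),
                 if (length(leaked) > 3) ", ..." else ""), call. = FALSE)
  }
  target <- model$cfg$target
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    i <- match(ids[k], manifest$sample_id)
    if (is.na(i)) stop("id not in manifest: ", ids[k], call. = FALSE)
    sm <- load_manifest_sample(manifest, i)
    pp <- prepare_sample(sm, model$arch$input_size, model$window, target)
    fw <- net_forward(model$net, pp$x, training = FALSE)
    m <- evaluate_case(fw$prob[, , 1, 1], pp$y, threshold = threshold)
    rows[[k]] <- dplyr::bind_cols(tibble::tibble(case_id = ids[k]), m)
  }
  cases <- dplyr::bind_rows(rows)
  agg <- aggregate_metrics(cases)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(cases, file.path(out_dir, "cases.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(agg), file.path(out_dir, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, aggregate = agg)
}
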