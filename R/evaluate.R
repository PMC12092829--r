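# Evaluation: per-class intersection-over-union and the stage-stratified
# cross-validation bookkeeping (one validation cell per division stage per
# case, validation cells disjoint across cases).

#' Intersection over union for one class
#'
#' `IoU_c = |pred == c  AND  truth == c| / |pred == c  OR  truth == c|`.
#' When the class is absent from both volumes the union is empty and the
#' score is undefined: `NA` is returned (never 0), and such entries are
#' excluded from averages.
#'
#' @param pred,truth Aligned [label_volume()]s (or integer arrays).
#' @param class_id Class code 0..5.
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @export
iou <- function(pred, truth, class_id) {
  p <- if (inherits(pred, "sbf_labels")) pred$data else pred
  t <- if (inherits(truth, "sbf_labels")) truth$data else truth
  stopifnot_same_shape(p, t)
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 0L || class_id > 5L)
    stop("class_id must be in 0..5")
  pm <- p == class_id
  tm <- t == class_id
  inter <- sum(pm & tm)
  uni <- sum(pm | tm)
  if (uni == 0L) return(NA_real_)
  inter / uni
}

#' Per-class IoU of one predicted volume
#'
#' @param pred,truth Aligned [label_volume()]s.
#' @return A data.frame with one row per class: `class_id`, `class`, `iou`
#'   (`NA` when undefined), `defined`, and voxel counts in prediction and
#'   truth.
#' @export
evaluate_volume <- function(pred, truth) {
  p <- if (inherits(pred, "sbf_labels")) pred$data else pred
  t <- if (inherits(truth, "sbf_labels")) truth$data else truth
  stopifnot_same_shape(p, t)
  rows <- lapply(seq_along(sbf_classes), function(i) {
    cid <- sbf_classes[[i]]
    val <- iou(p, t, cid)
    data.frame(class_id = cid, class = names(sbf_classes)[i],
               iou = val, defined = !is.na(val),
               pred_voxels = sum(p == cid), truth_voxels = sum(t == cid))
  })
  do.call(rbind, rows)
}

#' Mean IoU over defined entries
#'
#' Averages IoU over the requested classes, skipping undefined (class absent
#' from both volumes) entries rather than counting them as 0.
#'
#' @param metrics A data.frame from [evaluate_volume()].
#' @param classes Class codes to include (default: the five foreground
#'   classes 1..5).
#' @return Mean IoU, or `NA` if no included entry is defined.
#' @export
mean_iou <- function(metrics, classes = 1:5) {
  m <- metrics[metrics$class_id %in% classes & metrics$defined, ]
  if (!nrow(m)) return(NA_real_)
  mean(m$iou)
}

#' Build a stage-stratified cross-validation plan
#'
#' Each case holds out one validation cell per division stage (five cells
#' per case) and trains on all remaining cells; validation cells never
#' repeat across cases.
#'
#' @param cells A data.frame with columns `cell_id` and `stage` (1..5).
#' @param n_cases Number of cross-validation cases.
#' @param seed RNG seed; the plan is deterministic given it.
#' @param allow_empty_training If the pool is so small that a case's
#'   training set would be empty, `TRUE` downgrades the error to a warning.
#' @return An `sbf_split_plan`: list of cases, each with `validation` and
#'   `training` data.frames.
#' @export
make_split_plan <- function(cells, n_cases, seed = 1L,
                            allow_empty_training = FALSE) {
  stopifnot(is.data.frame(cells), all(c("cell_id", "stage") %in% names(cells)))
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  if (!all(cells$stage %in% 1:5)) stop("stages must be in 1..5")
  n_cases <- as.integer(n_cases)
  withr::local_seed(seed)
  picks <- list()
  for (s in 1:5) {
    ids <- cells$cell_id[cells$stage == s]
    if (length(ids) < n_cases)
      stop(sprintf("stage %d has %d cell(s); %d needed for %d cases",
                   s, length(ids), n_cases, n_cases))
    picks[[s]] <- ids[sample.int(length(ids))][seq_len(n_cases)]
  }
  cases <- lapply(seq_len(n_cases), function(k) {
    val_ids <- vapply(1:5, function(s) picks[[s]][k], cells$cell_id[1])
    validation <- cells[match(val_ids, cells$cell_id), ]
    training <- cells[!cells$cell_id %in% val_ids, ]
    if (nrow(training) == 0L) {
      msg <- sprintf("case %d has an empty training set", k)
      if (allow_empty_training) warning(msg) else stop(msg)
    } else {
      missing_stages <- setdiff(1:5, training$stage)
      if (length(missing_stages))
        warning(sprintf("case %d training set lacks stage(s) %s", k,
                        paste(missing_stages, collapse = ", ")))
    }
    list(validation = validation, training = training)
  })
  structure(list(cases = cases, seed = as.integer(seed)),
            class = "sbf_split_plan")
}

#' @export
print.sbf_split_plan <- function(x, ...) {
  cat(sprintf("stage-stratified split plan: %d case(s), %d validation cells each\n",
              length(x$cases), nrow(x$cases[[1]]$validation)))
  invisible(x)
}
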