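#' Meta-analytic spatial decoding of an eigenbrain against topic maps
#'
#' Ranks a set of labelled topic maps by their spatial correlation with an
#' eigenbrain over the brain mask. The analysis is descriptive by design:
#' interpretation rests on the directionality and relative strength of the
#' associations, and no p-values are emitted.
#'
#' @param eigenbrain a masked-voxel loading vector (length
#'   `n_mask_voxels(grid)`), a 3-D array on the grid, or a
#'   [subject_image()].
#' @param topics list of `topic_map` objects (fields `label`, `values`)
#'   with unique labels.
#' @param grid the [template_grid()].
#' @param method `"pearson"` (default, signed association strengths) or
#'   `"spearman"`.
#' @return data.frame of class `decoding_result` with columns `topic`,
#'   `r`, sorted by decreasing signed r.
#' @export
decode_eigenbrain <- function(eigenbrain, topics, grid,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(topics) < 1L) stop("need at least one topic map")
  labels <- vapply(topics, function(t) t$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate topic labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  eb <- if (inherits(eigenbrain, "subject_image")) flatten(eigenbrain, grid)
        else if (is.array(eigenbrain) && length(dim(eigenbrain)) == 3L)
          eigenbrain[mask_indices(grid)]
        else as.numeric(eigenbrain)
  if (length(eb) != n_mask_voxels(grid))
    stop("eigenbrain length does not match the brain mask")
  if (stats::sd(eb) == 0) stop("eigenbrain has zero variance over the mask")
  r <- vapply(topics, function(t) {
    tv <- if (is.array(t$values)) t$values[mask_indices(grid)] else as.numeric(t$values)
    if (length(tv) != length(eb)) stop(sprintf("topic '%s' not on the grid", t$label))
    if (stats::sd(tv) == 0) stop(sprintf("topic '%s' has zero variance over the mask", t$label))
    stats::cor(eb, tv, method = method)
  }, numeric(1))
  out <- data.frame(topic = labels, r = r)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decoding_result", "data.frame")
  out
}

#' Read a directory of topic maps
#'
#' Expects one NIfTI per topic plus a labels CSV with columns `file` and
#' `label`.
#'
#' @param dir directory containing the maps.
#' @param labels_csv path to the labels table (default `labels.csv` inside
#'   `dir`).
#' @param grid the [template_grid()].
#' @return list of `topic_map` objects.
#' @export
read_topic_maps <- function(dir, grid, labels_csv = file.path(dir, "labels.csv")) {
  tab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(tab)))
    stop("labels CSV needs columns `file` and `label`")
  lapply(seq_len(nrow(tab)), function(i) {
    img <- read_subject_image(file.path(dir, tab$file[i]), grid,
                              subject_id = tab$label[i])
    structure(list(label = tab$label[i], values = img$values),
              class = "topic_map")
  })
}
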