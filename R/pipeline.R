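#' Score every annotated line of one image
#'
#' @param image a [gray_image].
#' @param annotations list of [line_annotation] for this image.
#' @param q percentile threshold; default 89.
#' @param step sampling spacing in pixels; default 1.
#' @param ... passed to [score_line] (`x_convention`, `regression_mode`).
#' @return data frame with one row per line:
#'   `image_id,line_index,q,m1,m2,m3,raw_slope,normalized_slope,valid`.
#' @export
score_image <- function(image, annotations, q = 89, step = 1, ...) {
  rows <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    r <- score_line(sample_line(image, a, step = step), q = q, ...)
    data.frame(image_id = a$image_id, line_index = i, q = q,
               m1 = r$filtered_means[1], m2 = r$filtered_means[2],
               m3 = r$filtered_means[3], raw_slope = r$raw_slope,
               normalized_slope = r$normalized_slope, valid = r$valid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# rebuild slope_result-shaped records from a per-line data frame
lines_df_to_results <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    structure(list(raw_slope = df$raw_slope[i],
                   normalized_slope = df$normalized_slope[i],
                   valid = df$valid[i]),
              class = "slope_result"))
}

#' Score a cohort directory
#'
#' Runs the full measurement over a directory produced by [generate_cohort]
#' (or laid out the same way): a `manifest.csv` with
#' `image_id,sample_id,group,cohort`, an `annotations.json`, and one
#' grayscale image `<image_id>.tif` (or `.png`) per manifest row.
#'
#' @param dir cohort directory.
#' @param q percentile threshold; default 89.
#' @param step sampling spacing in pixels; default 1.
#' @param ... passed to [score_line].
#' @return list with `lines` (per-line data frame) and `samples` (per-sample
#'   data frame from [aggregate_sample], with `cohort` carried along).
#' @export
score_cohort_dir <- function(dir, q = 89, step = 1, ...) {
  manifest_path <- file.path(dir, "manifest.csv")
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(manifest_path)) stop("missing manifest: ", manifest_path)
  if (!file.exists(ann_path)) stop("missing annotations: ", ann_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  anns <- read_annotations(ann_path)
  ann_ids <- vapply(anns, `[[`, "", "image_id")
  score_cohort(manifest, anns, ann_ids,
               image_loader = function(image_id) {
                 p <- file.path(dir, paste0(image_id, ".tif"))
                 if (!file.exists(p))
                   p <- file.path(dir, paste0(image_id, ".png"))
                 if (!file.exists(p))
                   stop("image file missing for manifest entry '",
                        image_id, "'")
                 read_gray_image(p)
               },
               q = q, step = step, ...)
}

#' Score an in-memory cohort
#'
#' Same computation as [score_cohort_dir] for a cohort kept in memory
#' (e.g. the return value of [generate_cohort] with `out_dir = NULL`).
#'
#' @param cohort a [generate_cohort] result.
#' @param q,step,... as in [score_cohort_dir].
#' @return list with `lines` and `samples` data frames.
#' @export
score_cohort_memory <- function(cohort, q = 89, step = 1, ...) {
  anns <- unlist(lapply(cohort$phantoms, `[[`, "annotations"),
                 recursive = FALSE)
  ann_ids <- vapply(anns, `[[`, "", "image_id")
  images <- stats::setNames(lapply(cohort$phantoms, `[[`, "image"),
                            cohort$manifest$image_id)
  score_cohort(cohort$manifest, anns, ann_ids,
               image_loader = function(image_id) images[[image_id]],
               q = q, step = step, ...)
}

score_cohort <- function(manifest, anns, ann_ids, image_loader,
                         q = 89, step = 1, ...) {
  lines <- NULL
  samples <- NULL
  for (i in seq_len(nrow(manifest))) {
    iid <- manifest$image_id[i]
    a <- anns[ann_ids == iid]
    if (length(a) == 0)
      stop("no annotations for manifest image '", iid, "'")
    img <- image_loader(iid)
    ldf <- score_image(img, a, q = q, step = step, ...)
    lines <- rbind(lines, ldf)
    srow <- aggregate_sample(lines_df_to_results(ldf),
                             manifest$sample_id[i], manifest$group[i])
    srow$cohort <- manifest$cohort[i]
    samples <- rbind(samples, srow)
  }
  list(lines = lines, samples = samples)
}
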