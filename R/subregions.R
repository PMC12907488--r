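#' The twelve ventricular subregion classes
#'
#' Fixed taxonomy of the ventricular system used throughout the pipeline:
#' the bodies of both lateral ventricles, the third and fourth ventricle, and
#' the anterior horn, atrium, posterior horn and temporal horn of each side.
#' Class ids are 0-based and their order is fixed; label volumes code class
#' `id` as voxel value `id + 1` with 0 reserved for background.
#'
#' @return A data.frame with columns `id` (integer 0-11), `name`,
#'   `laterality` (`"left"`, `"right"` or `"midline"`), and `model_key`
#'   (the segmentation model each class resolves to; the two posterior horns
#'   share the pooled `"posterior_horns"` model).
#' @export
#' @examples
#' subregion_classes()
subregion_classes <- function() {
  df <- data.frame(
    id = 0:11,
    name = c(
      "body_right_lateral", "body_left_lateral",
      "third_ventricle", "fourth_ventricle",
      "right_anterior_horn", "right_atrium",
      "right_posterior_horn", "right_temporal_horn",
      "left_anterior_horn", "left_atrium",
      "left_posterior_horn", "left_temporal_horn"
    ),
    laterality = c(
      "right", "left", "midline", "midline",
      "right", "right", "right", "right",
      "left", "left", "left", "left"
    ),
    stringsAsFactors = FALSE
  )
  df$model_key <- ifelse(grepl("posterior_horn", df$name), "posterior_horns", df$name)
  df
}

#' @rdname subregion_classes
#' @param name subregion name(s)
#' @export
subregion_id <- function(name) {
  cls <- subregion_classes()
  i <- match(name, cls$name)
  if (anyNA(i)) stop("unknown subregion name: ", paste(name[is.na(i)], collapse = ", "))
  cls$id[i]
}

#' @rdname subregion_classes
#' @param id subregion id(s), 0-11
#' @export
subregion_name <- function(id) {
  cls <- subregion_classes()
  i <- match(id, cls$id)
  if (anyNA(i)) stop("unknown subregion id: ", paste(id[is.na(i)], collapse = ", "))
  cls$name[i]
}

#' Volume grouping of the ventricular system
#'
#' Groups used for reporting: the entire internal ventricular system, the left
#' and right sides (anterior horn, body of the lateral ventricle, atrium, and
#' temporal horn of that side), and the midline regions (third and fourth
#' ventricle). Note the posterior horns belong to the whole system but to
#' neither side group.
#'
#' @return Named list of integer class-id vectors.
#' @export
subregion_groups <- function() {
  list(
    whole_system = 0:11,
    right_side = subregion_id(c(
      "right_anterior_horn", "body_right_lateral",
      "right_atrium", "right_temporal_horn"
    )),
    left_side = subregion_id(c(
      "left_anterior_horn", "body_left_lateral",
      "left_atrium", "left_temporal_horn"
    )),
    midline = subregion_id(c("third_ventricle", "fourth_ventricle"))
  )
}

# priority used when fusing overlapping per-class predictions:
# smaller / rarer structures win over larger ones.
fusion_priority_order <- function() {
  cls <- subregion_classes()
  rank_of <- c(
    posterior_horn = 1, temporal_horn = 2, atrium = 3,
    anterior_horn = 4, third = 5, fourth = 6, body = 7
  )
  key <- rep(NA_real_, nrow(cls))
  key[grepl("posterior_horn", cls$name)] <- rank_of["posterior_horn"]
  key[grepl("temporal_horn", cls$name)] <- rank_of["temporal_horn"]
  key[grepl("atrium", cls$name)] <- rank_of["atrium"]
  key[grepl("anterior_horn", cls$name)] <- rank_of["anterior_horn"]
  key[cls$name == "third_ventricle"] <- rank_of["third"]
  key[cls$name == "fourth_ventricle"] <- rank_of["fourth"]
  key[grepl("^body_", cls$name)] <- rank_of["body"]
  cls$id[order(key, cls$id)]
}
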