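# MS COCO detection JSON I/O (images / annotations / categories, bbox as
# [x, y, w, h] in pixels).

#' Convert between COCO xywh and corner boxes
#'
#' @param boxes data frame with `x, y, w, h` (COCO) or
#'   `x_min, y_min, x_max, y_max` columns.
#' @return the data frame in the other convention.
#' @export
coco_to_xyxy <- function(boxes) {
  data.frame(x_min = boxes$x, y_min = boxes$y,
             x_max = boxes$x + boxes$w, y_max = boxes$y + boxes$h)
}

#' @rdname coco_to_xyxy
#' @export
xyxy_to_coco <- function(boxes) {
  data.frame(x = boxes$x_min, y = boxes$y_min,
             w = boxes$x_max - boxes$x_min, h = boxes$y_max - boxes$y_min)
}

#' Write a COCO detection annotation file
#'
#' @param images data frame with `id, file_name, width, height`.
#' @param annotations data frame with `id, image_id, bbox` columns `x, y, w,
#'   h` (one row per box) and optional `category_id` (default 1).
#' @param path output JSON path.
#' @param categories data frame with `id, name`.
#' @export
write_coco <- function(images, annotations, path,
                       categories = data.frame(id = 1L, name = "oedema")) {
  ann_list <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    list(id = as.integer(a$id), image_id = as.integer(a$image_id),
         category_id = as.integer(if (is.null(a$category_id)) 1L else a$category_id),
         bbox = c(a$x, a$y, a$w, a$h), area = a$w * a$h, iscrowd = 0L)
  })
  img_list <- lapply(seq_len(nrow(images)), function(i) {
    m <- images[i, ]
    list(id = as.integer(m$id), file_name = m$file_name,
         width = as.integer(m$width), height = as.integer(m$height))
  })
  cat_list <- lapply(seq_len(nrow(categories)), function(i) {
    list(id = as.integer(categories$id[i]), name = categories$name[i])
  })
  jsonlite::write_json(list(images = img_list, annotations = ann_list,
                            categories = cat_list),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Validate a COCO annotation structure
#'
#' Checks the detection-schema essentials: the three top-level sections,
#' required fields, unique ids, positive box extents and boxes inside their
#' image.
#'
#' @param coco a parsed COCO list (see [read_coco]).
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_coco <- function(coco) {
  for (sec in c("images", "annotations", "categories"))
    if (is.null(coco[[sec]])) stop("missing COCO section: ", sec)
  img_ids <- vapply(coco$images, `[[`, 1, "id")
  if (anyDuplicated(img_ids)) stop("duplicate image ids")
  for (m in coco$images)
    for (f in c("id", "file_name", "width", "height"))
      if (is.null(m[[f]])) stop("image entry missing field: ", f)
  ann_ids <- vapply(coco$annotations, `[[`, 1, "id")
  if (anyDuplicated(ann_ids)) stop("duplicate annotation ids")
  dims <- do.call(rbind, lapply(coco$images, function(m)
    c(m$id, m$width, m$height)))
  for (a in coco$annotations) {
    for (f in c("id", "image_id", "category_id", "bbox"))
      if (is.null(a[[f]])) stop("annotation entry missing field: ", f)
    bb <- as.numeric(a$bbox)
    if (length(bb) != 4L) stop("bbox must have 4 entries")
    if (bb[3] <= 0 || bb[4] <= 0) stop("bbox extents must be positive")
    wh <- dims[dims[, 1] == a$image_id, , drop = FALSE]
    if (nrow(wh) != 1L) stop("annotation references unknown image id")
    if (bb[1] < 0 || bb[2] < 0 || bb[1] + bb[3] > wh[1, 2] ||
        bb[2] + bb[4] > wh[1, 3])
      stop("bbox outside image bounds")
  }
  cat_ids <- vapply(coco$categories, `[[`, 1, "id")
  if (!all(vapply(coco$annotations, `[[`, 1, "category_id") %in% cat_ids))
    stop("annotation category not in categories")
  invisible(TRUE)
}

#' Write detections in COCO results format
#'
#' @param dets_by_image named list: image id -> detection data frame with
#'   `x_min, y_min, x_max, y_max, score`.
#' @param path output JSON path.
#' @export
write_coco_detections <- function(dets_by_image, path) {
  out <- list()
  for (id in names(dets_by_image)) {
    d <- dets_by_image[[id]]
    if (is.null(d) || nrow(d) == 0L) next
    cc <- xyxy_to_coco(d)
    for (i in seq_len(nrow(d))) {
      out[[length(out) + 1L]] <- list(
        image_id = as.integer(id), category_id = 1L,
        bbox = c(cc$x[i], cc$y[i], cc$w[i], cc$h[i]), score = d$score[i])
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
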