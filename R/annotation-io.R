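# Annotation and image IO: YOLO-format label text, VOC-style XML, manifest
# CSVs and 8-bit PNG round-tripping.

#' Class vocabulary
#'
#' The closed set of object classes: leaves plus the five pod types (a type-t
#' pod holds t seeds).
#'
#' @return Character vector `c("leaf", "pod1", ..., "pod5")`.
#' @export
class_vocabulary <- function() c("leaf", paste0("pod", 1:5))

check_classes <- function(cls) {
  bad <- setdiff(unique(as.character(cls)), class_vocabulary())
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  invisible(cls)
}

empty_boxes <- function(confidence = FALSE) {
  df <- data.frame(class = character(0), x_min = numeric(0),
                   y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
                   stringsAsFactors = FALSE)
  if (confidence) df$confidence <- numeric(0)
  df
}

#' Read and write YOLO-format labels
#'
#' YOLO label text holds one `class_index cx cy w h` line per box, with
#' center-form coordinates normalized by image width and height. Class
#' indices map to [class_vocabulary()] in order (0 = leaf, 1 = pod1, ...).
#' An optional sixth column carries prediction confidence.
#'
#' @param path Label file path.
#' @param image_w,image_h Image size in pixels, used to denormalize.
#' @return `read_yolo_labels()`: data frame with columns `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max` (and `confidence` if present in the file).
#' @export
read_yolo_labels <- function(path, image_w, image_h) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_boxes())
  parts <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nf <- lengths(parts)
  if (any(nf != 5L & nf != 6L))
    stop("malformed YOLO label line in ", path)
  m <- do.call(rbind, lapply(parts, function(p) c(p, rep(NA, 6 - length(p)))))
  cls_idx <- as.integer(m[, 1L])
  if (any(cls_idx < 0L | cls_idx >= length(class_vocabulary())))
    stop("class index out of range in ", path)
  cx <- m[, 2L] * image_w; cy <- m[, 3L] * image_h
  w <- m[, 4L] * image_w; h <- m[, 5L] * image_h
  df <- data.frame(class = class_vocabulary()[cls_idx + 1L],
                   x_min = cx - w / 2, y_min = cy - h / 2,
                   x_max = cx + w / 2, y_max = cy + h / 2,
                   stringsAsFactors = FALSE)
  if (all(!is.na(m[, 6L]))) df$confidence <- m[, 6L]
  df
}

#' @rdname read_yolo_labels
#' @param boxes Data frame with columns `class`, `x_min`, `y_min`, `x_max`,
#'   `y_max` and optionally `confidence`.
#' @export
write_yolo_labels <- function(boxes, path, image_w, image_h) {
  check_classes(boxes$class)
  idx <- match(boxes$class, class_vocabulary()) - 1L
  cx <- (boxes$x_min + boxes$x_max) / 2 / image_w
  cy <- (boxes$y_min + boxes$y_max) / 2 / image_h
  w <- (boxes$x_max - boxes$x_min) / image_w
  h <- (boxes$y_max - boxes$y_min) / image_h
  lines <- sprintf("%d %.10g %.10g %.10g %.10g", idx, cx, cy, w, h)
  if (!is.null(boxes$confidence))
    lines <- paste(lines, sprintf("%.10g", boxes$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write VOC-style XML annotations
#'
#' Pascal-VOC annotation XML: one `<object>` per box with `<name>` and a
#' `<bndbox>` of corner coordinates.
#'
#' @param path XML file path.
#' @return `read_voc_xml()`: data frame with `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, plus attributes `image_w`/`image_h` when a `<size>`
#'   element is present.
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, xp)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, xp)))
  if (length(objs) == 0L) {
    df <- empty_boxes()
  } else {
    df <- data.frame(
      class = vapply(objs, function(o)
        xml2::xml_text(xml2::xml_find_first(o, "./name")), character(1)),
      x_min = vapply(objs, get_num, numeric(1), "./bndbox/xmin"),
      y_min = vapply(objs, get_num, numeric(1), "./bndbox/ymin"),
      x_max = vapply(objs, get_num, numeric(1), "./bndbox/xmax"),
      y_max = vapply(objs, get_num, numeric(1), "./bndbox/ymax"),
      stringsAsFactors = FALSE)
  }
  size <- xml2::xml_find_first(doc, "./size")
  if (!inherits(size, "xml_missing")) {
    attr(df, "image_w") <- get_num(size, "./width")
    attr(df, "image_h") <- get_num(size, "./height")
  }
  df
}

#' @rdname read_voc_xml
#' @param boxes Box data frame as above.
#' @param image_w,image_h Image size in pixels, written to `<size>`.
#' @param filename Value for the `<filename>` element.
#' @export
write_voc_xml <- function(boxes, path, image_w, image_h,
                          filename = basename(path)) {
  check_classes(boxes$class)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_w))
  xml2::xml_add_child(size, "height", as.character(image_h))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", boxes$class[i])
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(boxes$x_min[i]))
    xml2::xml_add_child(bb, "ymin", format(boxes$y_min[i]))
    xml2::xml_add_child(bb, "xmax", format(boxes$x_max[i]))
    xml2::xml_add_child(bb, "ymax", format(boxes$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read and write 8-bit PNG images
#'
#' Images are handled internally as numeric arrays in \[0, 1\];
#' `write_image()` quantizes to 8 bits with round-half-even before encoding.
#'
#' @param path PNG file path.
#' @return `read_image()`: numeric array in \[0, 1\].
#' @export
read_image <- function(path) png::readPNG(path)

#' @rdname read_image
#' @param image Numeric array in \[0, 1\].
#' @export
write_image <- function(image, path) {
  png::writePNG(round(pmin(pmax(image, 0), 1) * 255) / 255, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest CSV maps each image to its label file and experimental unit:
#' columns `image`, `label_file`, `width`, `height`, `pot_id`, `view`.
#'
#' @param path Manifest CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
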