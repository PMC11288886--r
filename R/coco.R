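# COCO-style detection ground-truth JSON: images, annotations with
# [x, y, w, h] boxes, categories. Internal boxes are half-open
# [x0, x1) x [y0, y1) with 0-based pixel coordinates, so x = x0, w = x1 - x0.

#' Write detection ground truth as COCO-style JSON
#'
#' @param boxes_per_image list of data.frame(class_id, x0, y0, x1, y1).
#' @param heights,widths per-image sizes.
#' @param path output file.
#' @param categories optional character vector of category names.
#' @export
write_coco_boxes <- function(boxes_per_image, heights, widths, path,
                             categories = NULL) {
  n <- length(boxes_per_image)
  images <- lapply(seq_len(n), function(i)
    list(id = i, height = heights[i], width = widths[i],
         file_name = sprintf("%04d.png", i)))
  anns <- list()
  aid <- 0L
  for (i in seq_len(n)) {
    b <- boxes_per_image[[i]]
    if (!nrow(b)) next
    for (j in seq_len(nrow(b))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = i,
                          category_id = b$class_id[j] + 1L,
                          bbox = c(b$x0[j], b$y0[j],
                                   b$x1[j] - b$x0[j], b$y1[j] - b$y0[j]),
                          area = (b$x1[j] - b$x0[j]) * (b$y1[j] - b$y0[j]),
                          iscrowd = 0L)
    }
  }
  cids <- sort(unique(unlist(lapply(boxes_per_image, function(b)
    if (nrow(b)) b$class_id else integer(0))))) + 1L
  if (is.null(categories)) categories <- paste0("class", cids - 1L)
  cats <- lapply(seq_along(cids), function(k)
    list(id = cids[k], name = categories[k]))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style detection ground truth
#'
#' @param path JSON file written in the COCO layout.
#' @return list of data.frame(class_id, x0, y0, x1, y1), one per image id.
#' @export
read_coco_boxes <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  nimg <- length(d$images)
  out <- replicate(nimg, data.frame(class_id = integer(0), x0 = numeric(0),
                                    y0 = numeric(0), x1 = numeric(0),
                                    y1 = numeric(0)), simplify = FALSE)
  for (a in d$annotations) {
    i <- a$image_id
    bb <- unlist(a$bbox)
    row <- data.frame(class_id = a$category_id - 1L, x0 = bb[1], y0 = bb[2],
                      x1 = bb[1] + bb[3], y1 = bb[2] + bb[4])
    out[[i]] <- rbind(out[[i]], row)
  }
  out
}
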