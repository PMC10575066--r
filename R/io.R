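# File formats: 8-bit PNG (and JPEG) images, single-channel PNG masks with
# 0 = background and 255 = crop, a tab-separated manifest, and a minimal
# polygon-annotation JSON dialect.

png_bit_depth <- function(path) {
  # bit depth lives at byte 25 of the file: 8-byte signature, 8-byte chunk
  # header, 4+4 bytes of IHDR width/height.
  hdr <- readBin(path, "raw", 25L)
  if (length(hdr) < 25L) stop_input("not a PNG file: ", path)
  as.integer(hdr[25L])
}

#' Read an image file as a unit-range image tensor
#'
#' Supports 8-bit 3-channel PNG (and JPEG when the jpeg package is
#' available).  Pixel values are normalized to `[0, 1]` on read; 16-bit
#' PNGs are rejected with an explicit unsupported-depth error.
#'
#' @param path image file.
#' @param space color-space tag to attach (`"rgb"` for camera images;
#'   `"hsv"` when reading a stored HSV view).
#' @return An [image_tensor].
#' @export
read_image <- function(path, space = "rgb") {
  if (!file.exists(path)) stop_input("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    if (depth != 8L)
      stop_input("unsupported bit depth ", depth, " in ", path,
                 " (only 8-bit images are supported)")
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_input("reading JPEG requires the 'jpeg' package: ", path)
    x <- jpeg::readJPEG(path)
  } else {
    stop_input("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(x)[3] != 3)
    stop_input("expected a 3-channel image, got ", dim(x)[3], " channel(s): ", path)
  image_tensor(x, space)
}

#' Write an image tensor as an 8-bit PNG
#'
#' Values are quantized round-half-up to 8 bits; writing then reading an
#' 8-bit-exact image is lossless.
#'
#' @param img an [image_tensor].
#' @param path output PNG path.
#' @export
write_image <- function(img, path) {
  x <- floor(unclass(img) * 255 + 0.5) / 255
  png::writePNG(x, path)
  invisible(path)
}

#' Read or write a binary mask PNG
#'
#' Masks are single-channel PNGs with 0 = background and 255 = crop; on
#' read any value above 127 maps to crop (1).
#'
#' @param path mask PNG path.
#' @param mask integer 0/1 matrix.
#' @return `read_mask()` returns an integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_input("cannot read mask: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(x > 0.5), nrow(x), ncol(x))
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Rasterize polygon annotations into a binary mask
#'
#' Fills the union of polygon interiors with crop (1) using the even-odd
#' rule, testing each pixel center.  Polygon vertices are `(x, y)` pairs in
#' image convention (x = column, y = row, 0-based, origin top-left); pixel
#' `(row r, col c)` (1-based) has center `(c - 0.5, r - 0.5)`.
#'
#' @param polygons list of closed point sequences; each an `n x 2` matrix
#'   (n >= 3) of `(x, y)` vertices.
#' @param height,width canvas size in pixels.
#' @return An integer 0/1 mask of dimension `height x width`.
#' @examples
#' rect <- matrix(c(1, 1, 4, 1, 4, 3, 1, 3), ncol = 2, byrow = TRUE)
#' sum(mask_from_polygons(list(rect), 6, 6))   # 3 x 2 interior cells
#' @export
mask_from_polygons <- function(polygons, height, width) {
  if (!is_count(height, 1) || !is_count(width, 1))
    stop_input("`height` and `width` must be positive integers")
  mask <- matrix(FALSE, height, width)
  px <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  py <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3) stop_input("degenerate polygon with fewer than 3 vertices")
    crossings <- matrix(0L, height, width)
    n <- nrow(poly)
    for (e in seq_len(n)) {
      p1 <- poly[e, ]; p2 <- poly[if (e == n) 1L else e + 1L, ]
      spans <- (p1[2] <= py) != (p2[2] <= py)
      if (!any(spans)) next
      xcut <- p1[1] + (py - p1[2]) / (p2[2] - p1[2]) * (p2[1] - p1[1])
      crossings <- crossings + as.integer(spans & px < xcut)
    }
    mask <- mask | (crossings %% 2L == 1L)
  }
  matrix(as.integer(mask), height, width)
}

#' Read a polygon-annotation JSON file
#'
#' Minimal annotation dialect: an object with `height`, `width` and a
#' `shapes` array whose entries carry a `label` and a `points` list of
#' `(x, y)` vertices.  Shapes labeled `"crop"` (or everything, when no
#' shape carries that label) are rasterized into the crop mask.
#'
#' @param path JSON annotation file.
#' @return A list with `height`, `width`, `polygons` and the rasterized
#'   `mask`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_input("cannot read annotation: ", path)
  a <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(a$height) || is.null(a$width) || is.null(a$shapes))
    stop_input("annotation lacks height/width/shapes: ", path)
  polys <- lapply(a$shapes, function(s)
    do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p)))))
  labels <- vapply(a$shapes, function(s)
    if (is.null(s$label)) "crop" else as.character(s$label), "")
  keep <- if (any(labels == "crop")) labels == "crop" else rep(TRUE, length(polys))
  list(height = as.integer(a$height), width = as.integer(a$width),
       polygons = polys[keep],
       mask = mask_from_polygons(polys[keep], a$height, a$width))
}

# ---- dataset layout ------------------------------------------------------
# root/
#   rgb/ITEM.png  hsv/ITEM.png  mask/ITEM.png  manifest.tsv (file, split, scene)

#' Write a segmentation dataset as a directory layout
#'
#' Creates `rgb/`, `hsv/` and `mask/` subtrees of 8-bit PNGs plus a
#' tab-separated `manifest.tsv` listing every item's file name, split tag
#' and base-scene id.  Images are 8-bit quantized on write.
#'
#' @param ds a [seg_dataset].
#' @param dir target directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "seg_dataset"))
  for (sub in c(names(ds$views), "mask"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("item_%05d.png", seq_along(ds$masks))
  for (i in seq_along(ds$masks)) {
    for (v in names(ds$views))
      write_image(ds$views[[v]][[i]], file.path(dir, v, files[i]))
    write_mask(ds$masks[[i]], file.path(dir, "mask", files[i]))
  }
  manifest <- data.frame(file = files,
                         split = ifelse(is.na(ds$split), "none", ds$split),
                         scene = ifelse(is.na(ds$scene), -1L, ds$scene))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory layout
#'
#' Re-reads a layout written by [write_dataset()]; every manifest entry
#' must resolve to existing, dimension-matched files in all subtrees.
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return A [seg_dataset].
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path)) stop_input("no manifest at ", mf_path)
  mf <- read.delim(mf_path, stringsAsFactors = FALSE)
  view_names <- intersect(c("rgb", "hsv"), list.dirs(dir, recursive = FALSE,
                                                     full.names = FALSE))
  if (!length(view_names)) stop_input("no view subdirectories under ", dir)
  views <- lapply(view_names, function(v)
    lapply(mf$file, function(f) {
      p <- file.path(dir, v, f)
      if (!file.exists(p)) stop_input("manifest entry missing on disk: ", p)
      read_image(p, space = v)
    }))
  names(views) <- view_names
  masks <- lapply(mf$file, function(f) {
    p <- file.path(dir, "mask", f)
    if (!file.exists(p)) stop_input("manifest entry missing on disk: ", p)
    read_mask(p)
  })
  split <- ifelse(mf$split == "none", NA_character_, mf$split)
  scene <- if ("scene" %in% names(mf)) ifelse(mf$scene < 0, NA_integer_,
                                              mf$scene) else NULL
  seg_dataset(views, masks, split = split,
              scene = if (is.null(scene)) rep(NA_integer_, nrow(mf)) else scene)
}
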