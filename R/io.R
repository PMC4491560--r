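#' Write a labeled image set as a PNG directory tree
#'
#' Images land at `<root>/<superordinate>/<basic>/<subordinate>/<id>.png`
#' (the three path levels encode the taxonomy labels; unused levels are
#' the literal "-"), and a `manifest.csv` with columns id, path,
#' superordinate, basic, subordinate is written at the root.
#'
#' @param images List of `labeled_image` objects.
#' @param root Output directory.
#' @param overwrite Allow writing into an existing nonempty directory.
#' @return The manifest data.frame, invisibly.
#' @export
write_image_set <- function(images, root, overwrite = FALSE) {
  stopifnot(length(images) > 0)
  if (dir.exists(root) && length(list.files(root)) > 0 && !overwrite) {
    stop("output directory ", root,
         " is nonempty; use overwrite = TRUE", call. = FALSE)
  }
  if (!dir.exists(dirname(root))) {
    stop("parent directory ", dirname(root), " does not exist",
         call. = FALSE)
  }
  dir.create(root, showWarnings = FALSE)
  rows <- lapply(images, function(im) {
    lab <- im$label
    rel <- file.path(lab[1], lab[2], lab[3], paste0(im$id, ".png"))
    dir.create(file.path(root, dirname(rel)), recursive = TRUE,
               showWarnings = FALSE)
    png::writePNG(im$pixels, file.path(root, rel))
    data.frame(id = im$id, path = rel, superordinate = unname(lab[1]),
               basic = unname(lab[2]), subordinate = unname(lab[3]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a labeled image set written by [write_image_set()]
#'
#' @param root Dataset directory containing `manifest.csv`.
#' @return A list of `labeled_image` objects.
#' @export
read_image_set <- function(root) {
  mf <- file.path(root, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", root, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("empty dataset manifest", call. = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- to_grayscale(read_raster(file.path(root, manifest$path[i])))
    .labeled_image(px, manifest$superordinate[i], manifest$basic[i],
                   manifest$subordinate[i], manifest$id[i])
  })
}

#' Read a PNG, TIFF or JPEG raster
#'
#' @param path File path; format is dispatched on the extension.
#' @return A numeric matrix or array with values in \[0, 1\].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::readPNG(path),
         tif = ,
         tiff = tiff::readTIFF(path),
         jpg = ,
         jpeg = {
           if (!requireNamespace("jpeg", quietly = TRUE)) {
             stop("the jpeg package is required for JPEG input",
                  call. = FALSE)
           }
           jpeg::readJPEG(path)
         },
         stop("unsupported raster format: .", ext, call. = FALSE))
}

#' Persist an eigenspace model
#'
#' Stores mode, means, bases, eigenvalues and the vectorization
#' convention (column-major) in a single RDS archive.
#'
#' @param model An `eigenspace_model`.
#' @param path Output file.
#' @export
save_eigenspace_model <- function(model, path) {
  stopifnot(inherits(model, "eigenspace_model"))
  model$vectorization <- "column-major"
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_eigenspace_model
#' @return `load_eigenspace_model` returns the `eigenspace_model`.
#' @export
load_eigenspace_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "eigenspace_model"))
  model
}
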