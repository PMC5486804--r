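#' Write a dataset as PNG patches with a CSV manifest
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing); patches are written as
#'   `<patch_id>.png` next to `manifest.csv` (columns `path`, `label`,
#'   `patch_id`, `source_id`, `split`, `fold`).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$path <- paste0(man$patch_id, ".png")
  for (i in seq_along(dataset$patches))
    png::writePNG(dataset$patches[[i]]$pixels,
                  file.path(dir, man$path[i]))
  man <- man[, c("path", "label", "patch_id", "source_id", "split", "fold")]
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(man, out, row.names = FALSE)
  invisible(out)
}

#' Read patches from a PNG/TIFF directory with a CSV manifest
#'
#' The manifest must provide columns `path`, `label` and `patch_id`
#' (`source_id`, `split`, `fold` are optional and default to the patch id /
#' `"train"` / `NA`). RGB images are converted to gray by channel averaging.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return A `cell_dataset`.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  need <- c("path", "label", "patch_id")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(man$source_id)) man$source_id <- man$patch_id
  if (is.null(man$split)) man$split <- "train"
  if (is.null(man$fold)) man$fold <- NA_integer_
  patches <- lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(dir, man$path[i])
    px <- if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(f)
    } else png::readPNG(f)
    if (length(dim(px)) == 3) {
      to_grayscale(px[, , 1:3, drop = FALSE], label = man$label[i],
                   patch_id = man$patch_id[i])
    } else {
      gray_patch(px, label = man$label[i], patch_id = man$patch_id[i])
    }
  })
  structure(
    list(patches = patches,
         manifest = man[, c("patch_id", "label", "source_id", "split",
                            "fold")],
         specs = NULL, delta = NA_real_, side = patches[[1]]$side,
         seed = NA_integer_),
    class = "cell_dataset")
}

#' Save / load a trained classifier
#'
#' The model object is serialized with [saveRDS()] and a human-readable JSON
#' sidecar (`<path>.json`) records the hyper-parameters.
#'
#' @param model an `esn_classifier` or `rf_forest`.
#' @param path destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- if (inherits(model, "esn_classifier")) {
    c(model$esn$params,
      list(type = "esn", L = model$field$L, side = model$field$side,
           r = model$field$r, delta_phi = model$schedule$delta_phi,
           steps_per_image = model$schedule$steps_per_image,
           beta = model$beta, trim_fraction = model$trim_fraction,
           classes = model$classes))
  } else if (inherits(model, "rf_forest")) {
    c(model$hyper, list(type = "rf", K = model$K,
                        n_features = model$n_features, seed = model$seed))
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
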