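#' Read and write numeric matrices as full-precision CSV
#'
#' The package's canonical on-disk format for feature and response matrices
#' is plain CSV with an `id` column for stimulus ids and one column per
#' channel/voxel. Values are written with 17 significant digits, so a
#' write-read round trip reproduces doubles exactly.
#'
#' @param m Numeric matrix (row names become the `id` column; absent row
#'   names are written as `row_1 ...`).
#' @param path File path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns the matrix with dimnames restored.
#' @export
write_matrix_csv <- function(m, path) {
  check_finite_matrix(m, "m")
  ids <- rownames(m) %||% sprintf("row_%d", seq_len(nrow(m)))
  cols <- colnames(m) %||% sprintf("col_%d", seq_len(ncol(m)))
  body <- matrix(formatC(m, format = "g", digits = 17), nrow(m), ncol(m))
  lines <- c(paste(c("id", cols), collapse = ","),
             paste(ids, apply(body, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (!"id" %in% names(df))
    stop(sprintf("%s is not a matrix CSV (missing 'id' column)", path),
         call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("%s contains non-numeric entries", path), call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' Read and write ROI voxel-index files
#'
#' ROI files are JSON objects mapping ROI names to arrays of voxel ids
#' (strings) or 0-based voxel indices (numbers). Overlapping ROIs are
#' accepted; the overlap is reported.
#'
#' @param rois Named list mapping ROI name to a character vector of voxel ids
#'   or an integer vector of indices.
#' @param path File path.
#' @return `read_roi_json` returns the named list.
#' @export
write_roi_json <- function(rois, path) {
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("rois must be a fully named list", call. = FALSE)
  jsonlite::write_json(rois, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  rois <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(rois) || is.null(names(rois)))
    stop(sprintf("%s is not a ROI JSON object", path), call. = FALSE)
  all_vox <- unlist(rois)
  dup <- unique(all_vox[duplicated(all_vox)])
  if (length(dup))
    message(sprintf("ROI file has %d voxel(s) in more than one ROI", length(dup)))
  rois
}

#' Persist and reload a fitted encoding model
#'
#' Saves an `encoding_model` as a directory of text artifacts: `kernels.csv`
#' (channels x voxels), `voxels.csv` (constants and per-voxel diagnostics),
#' `channels.csv` (standardization center/scale), and `meta.json` (the
#' training control and dimensions). The round trip is numerically exact.
#'
#' @param model An `encoding_model` from [fit_encoding()].
#' @param dir Directory to create/overwrite.
#' @return `load_encoding_model` returns the restored `encoding_model`.
#' @export
save_encoding_model <- function(model, dir) {
  stopifnot(inherits(model, "encoding_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(model$kernels, file.path(dir, "kernels.csv"))
  vox <- data.frame(id = model$voxel_ids,
                    constant = formatC(model$constants, format = "g", digits = 17),
                    iterations = model$diagnostics$iterations,
                    stop_mse = formatC(model$diagnostics$stop_mse,
                                       format = "g", digits = 17),
                    degenerate = model$diagnostics$degenerate)
  utils::write.csv(vox, file.path(dir, "voxels.csv"), row.names = FALSE,
                   quote = FALSE)
  chans <- data.frame(id = model$channel_ids %||%
                        sprintf("col_%d", seq_along(model$center)),
                      center = formatC(model$center, format = "g", digits = 17),
                      scale = formatC(model$scale, format = "g", digits = 17))
  utils::write.csv(chans, file.path(dir, "channels.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(class = "encoding_model", n_train = model$n_train,
               standardize = model$standardize,
               control = unclass(model$control))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_encoding_model
#' @export
load_encoding_model <- function(dir) {
  need <- file.path(dir, c("kernels.csv", "voxels.csv", "channels.csv",
                           "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop(sprintf("not an encoding-model directory (missing %s)",
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  kernels <- read_matrix_csv(need[1])
  vox <- utils::read.csv(need[2], check.names = FALSE)
  chans <- utils::read.csv(need[3], check.names = FALSE)
  meta <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  ctl <- do.call(train_control, meta$control)
  structure(list(kernels = kernels,
                 constants = stats::setNames(as.numeric(vox$constant), vox$id),
                 center = as.numeric(chans$center),
                 scale = as.numeric(chans$scale),
                 standardize = isTRUE(meta$standardize), control = ctl,
                 diagnostics = data.frame(voxel = vox$id,
                                          iterations = vox$iterations,
                                          stop_mse = as.numeric(vox$stop_mse),
                                          degenerate = vox$degenerate),
                 channel_ids = rownames(kernels), voxel_ids = vox$id,
                 n_train = meta$n_train, call = NULL),
            class = "encoding_model")
}

#' Write an identification result as JSON (plus optional matrix CSV)
#'
#' @param result An `identification_result` or a named list of them (the
#'   per-ROI form from [identify_by_roi()]).
#' @param path Output JSON path.
#' @param matrix_path Optional CSV path for the correlation matrix (single
#'   result only).
#' @return `path`, invisibly.
#' @export
write_identification_json <- function(result, path, matrix_path = NULL) {
  as_entry <- function(r)
    list(n_correct = r$n_correct, P = r$P, accuracy = r$accuracy,
         accuracy_percent = round(100 * r$accuracy, 1))
  payload <- if (inherits(result, "identification_result")) as_entry(result)
             else lapply(result, as_entry)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(matrix_path) && inherits(result, "identification_result"))
    write_matrix_csv(result$corr_matrix, matrix_path)
  invisible(path)
}

#' Read a directory of PNG images as a stimulus stack
#'
#' Files are taken in lexicographic order (which defines stimulus order) and
#' must share one size. Color PNGs are converted to grayscale by channel
#' averaging; pixel values arrive in `[0, 1]`.
#'
#' @param dir Directory containing `.png` files.
#' @return An `S x S x n` array with file names (sans extension) as stimulus
#'   ids.
#' @export
read_images_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no PNG files in %s", dir), call. = FALSE)
  imgs <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    a
  })
  d <- dim(imgs[[1]])
  if (d[1] != d[2])
    stop("images must be square", call. = FALSE)
  if (!all(vapply(imgs, function(a) identical(dim(a), d), logical(1))))
    stop("all images must share one size", call. = FALSE)
  out <- simplify2array(imgs)
  dimnames(out)[[3]] <- sub("\\.png$", "", basename(files))
  out
}
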