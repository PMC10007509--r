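# PNG image/mask I/O, dataset manifests, configs and model checkpoints.
# Images are exchanged as 8-bit grayscale (or RGB) PNG; masks as 0/255
# PNG. Internal computation stays in floating point [0,1]; quantization
# happens only at the I/O boundary (max round-trip error 1/255 for images,
# exact for masks).

#' Write an image (or mask) as 8-bit PNG
#'
#' @param img image in \[0, 1\] (matrix or H x W x 3 array). For masks,
#'   pass the binary mask; 1 is stored as 255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(img, path) {
  check_image(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read an 8-bit PNG image
#'
#' @param path PNG file path.
#' @param as_mask validate and return as a binary integer mask.
#' @return Matrix in \[0, 1\] (grayscale), H x W x 3 array (RGB), or a
#'   binary matrix when `as_mask = TRUE`.
#' @export
load_image_png <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) img <- img[, , 1]                 # gray+alpha
    else if (dim(img)[3] == 4) img <- img[, , 1:3]          # drop alpha
    else if (dim(img)[3] == 1) img <- img[, , 1]
  }
  if (as_mask) {
    m <- collapse_channels(img)
    if (!all(m %in% c(0, 1)))
      stop_invalid("mask file ", path, " is not binary")
    return(matrix(as.integer(m), nrow(m), ncol(m)))
  }
  img
}

#' Load all PNG images in a directory
#'
#' Files are read in lexicographic order and must share one size.
#'
#' @param dir directory containing `.png` files.
#' @return Named list of images.
#' @export
load_image_dir <- function(dir) {
  if (!dir.exists(dir)) stop_invalid("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_invalid("no PNG files in ", dir)
  imgs <- lapply(files, load_image_png)
  dims <- vapply(imgs, function(i) paste(dim(i)[1:2], collapse = "x"), "")
  if (length(unique(dims)) > 1)
    stop_invalid("mixed image sizes in ", dir, ": ",
                 paste(basename(files)[dims != dims[1]], collapse = ", "))
  names(imgs) <- basename(files)
  imgs
}

#' Write a split dataset to disk
#'
#' Lays out `train/`, `val/` and `test/` subdirectories of 8-bit PNGs
#' (test masks as `*_mask.png`) plus a `manifest.csv` with columns `path`,
#' `split`, `mask_path`, `lesion_area_px`, `seed`.
#'
#' @param dataset a `split_dataset`.
#' @param dir output directory (created).
#' @return The manifest data frame, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "split_dataset"))
  for (d in file.path(dir, c("train", "val", "test")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  wr <- function(split, i, img, mask = NULL, area = NA) {
    p <- file.path(dir, split, sprintf("%s_%04d.png", split, i))
    save_image_png(img, p)
    mp <- ""
    if (!is.null(mask)) {
      mp <- file.path(dir, split, sprintf("%s_%04d_mask.png", split, i))
      save_image_png(mask + 0, mp)
    }
    data.frame(path = p, split = split, mask_path = mp,
               lesion_area_px = area, seed = dataset$seed)
  }
  for (i in seq_along(dataset$train))
    rows[[length(rows) + 1]] <- wr("train", i, dataset$train[[i]])
  for (i in seq_along(dataset$val))
    rows[[length(rows) + 1]] <- wr("val", i, dataset$val[[i]])
  for (i in seq_along(dataset$test))
    rows[[length(rows) + 1]] <- wr("test", i, dataset$test[[i]]$image,
                                   dataset$test[[i]]$mask,
                                   dataset$test[[i]]$area_px)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a split dataset written by [save_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return A `split_dataset` (pixel values carry 8-bit quantization).
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_invalid("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  get <- function(split) manifest[manifest$split == split, , drop = FALSE]
  tr <- lapply(get("train")$path, load_image_png)
  va <- lapply(get("val")$path, load_image_png)
  te_rows <- get("test")
  te <- lapply(seq_len(nrow(te_rows)), function(i) {
    mask <- load_image_png(te_rows$mask_path[i], as_mask = TRUE)
    list(image = load_image_png(te_rows$path[i]), mask = mask,
         area_px = sum(mask))
  })
  d1 <- dim(if (length(tr)) tr[[1]] else te[[1]]$image)
  structure(list(train = tr, val = va, test = te,
                 height = d1[1], width = d1[2],
                 channels = if (length(d1) == 3) d1[3] else 1L,
                 seed = manifest$seed[1],
                 config = list(n_train = length(tr), n_val = length(va),
                               n_test = length(te))),
            class = "split_dataset")
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS file embedding the parameters, BatchNorm
#' state, architecture configuration, training history and seed, so a
#' loaded model is immediately usable for inference.
#'
#' @param object fitted [anomaly_autoencoder()].
#' @param path checkpoint file path (`.rds`).
#' @return `save_model()`: `path` invisibly; `load_model()`: the fit.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "anomaly_autoencoder"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("no such checkpoint: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "anomaly_autoencoder"))
    stop_invalid(path, " is not an anomaly_autoencoder checkpoint")
  obj
}

## ---- experiment configuration --------------------------------------------

#' Default experiment configuration
#'
#' Returns the full nested configuration for [run_experiment()]: the
#' phantom generator (`data`), the model list and architecture (`model`),
#' the training protocol (`train`), the evaluation thresholds
#' (`evaluate`), a global `seed` and an `output_dir`. Every field can be
#' overridden by the YAML file passed to [read_experiment_config()];
#' unknown keys are rejected.
#'
#' @return Nested named list.
#' @export
default_experiment_config <- function() {
  list(
    seed = 1,
    output_dir = "aedetect-run",
    data = list(n_train = 853, n_val = 94, n_test = 200,
                height = 64, width = 64, channels = 1,
                lesion_area_min_px = 50, lesion_area_max_px = 400,
                lesion_drop_min = 0.4, lesion_drop_max = 0.7,
                lesion_softness = 1, speckle_scale = 0.3, smoothness = 8),
    model = list(kinds = c("ae", "vae", "swae"), latent_dim = 32,
                 channels = c(8, 16, 32, 64), batchnorm = TRUE,
                 leaky_slope = 0.2, beta = 1, lambda = 10,
                 n_projections = 50),
    train = list(epochs = 150, batch_size = 16, lr = 2e-4, lr_min = 0,
                 augment_gamma = TRUE),
    evaluate = list(thresholds = c(0.1, 0.2, 0.3), include_relu_max = TRUE,
                    size_bins = 5),
    io = list(write_images = FALSE, write_checkpoints = TRUE))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop_invalid("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop_invalid("configuration key ", key, " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate an experiment configuration
#'
#' Loads a YAML file (or takes a list), overlays it on
#' [default_experiment_config()] and validates it: unknown keys and
#' malformed values are rejected before any work starts.
#'
#' @param config YAML file path, or a (possibly partial) configuration
#'   list; `NULL` gives the defaults.
#' @return Validated full configuration list.
#' @export
read_experiment_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
          else if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config
          else stop_invalid("config must be a YAML path or a list")
  cfg <- merge_config(default_experiment_config(), user)
  with(cfg$data, {
    if (any(c(n_train, n_val, n_test) < 1))
      stop_invalid("data counts must be >= 1")
  })
  if (!all(cfg$model$kinds %in% c("ae", "vae", "swae")))
    stop_invalid("model.kinds must be a subset of ae, vae, swae")
  if (cfg$train$epochs < 1 || cfg$train$batch_size < 1)
    stop_invalid("train.epochs and train.batch_size must be >= 1")
  cfg
}
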