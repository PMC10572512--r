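#' Handcrafted two-view feature extraction for desk-scale runs
#'
#' Stands in for pipeline stages that would normally consume per-sample CNN
#' feature CSVs: view A is per-channel intensity histograms, view B is
#' mask-region statistics (lesion/skin channel means and SDs, mask area
#' fraction, luminance summary and texture-residual summary). Any external
#' per-sample CSV can be substituted via [read_features_csv()].
#'
#' @param images list of `rgb_image` arrays (or lists with an `image`
#'   field, as returned by [make_lesion_image()]).
#' @param masks optional list of logical lesion masks; computed by
#'   [enhance()] when absent.
#' @param labels optional integer labels attached to both outputs.
#' @param bins histogram bins per channel for view A (default 8).
#' @return list with `Fa` and `Fb` `feature_matrix` objects.
#' @export
extract_features <- function(images, masks = NULL, labels = NULL, bins = 8L) {
  n <- length(images)
  breaks <- seq(0, 1, length.out = bins + 1L)
  fa <- matrix(0, n, 3L * bins)
  fb <- matrix(0, n, 17L)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (is.list(img) && !is.null(img$image)) img <- img$image
    mask <- if (!is.null(masks)) masks[[i]] else enhance(img)$mask
    if (!any(mask)) mask[which.min(rgb_to_luminance(img)$values)] <- TRUE
    hs <- numeric(0)
    for (ch in 1:3) {
      h <- hist(img[, , ch], breaks = breaks, plot = FALSE)$counts
      hs <- c(hs, h / sum(h))
    }
    fa[i, ] <- hs
    lum <- rgb_to_luminance(img)
    tex <- texture_residual(lum$values / 100, max(lum$sigma, 1))
    stats_ch <- numeric(0)
    for (ch in 1:3) {
      plane <- img[, , ch]
      stats_ch <- c(stats_ch, mean(plane[mask]), stats::sd(plane[mask]),
                    mean(plane[!mask]), stats::sd(plane[!mask]))
    }
    fb[i, ] <- c(stats_ch, mean(mask), mean(lum$values), lum$sigma,
                 mean(tex$values), stats::sd(tex$values))
  }
  fb[!is.finite(fb)] <- 0
  list(Fa = feature_matrix(fa, labels = labels, source = "hist"),
       Fb = feature_matrix(fb, labels = labels, source = "stat"))
}

#' Parse a plain-text key=value configuration file
#'
#' Lines look like `stage.key = value`; `#` starts a comment. Values are
#' converted to numeric where possible; comma-separated values become
#' vectors.
#'
#' @param path configuration file path.
#' @return nested named list, one element per stage.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!any(is.na(num))) num else parts
    ks <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(ks) == 2L) cfg[[ks[1]]][[ks[2]]] <- val else cfg[[key]] <- val
  }
  cfg
}

#' Run the full recognition pipeline on synthetic or provided data
#'
#' Stage order: image generation (or loading) -> contrast enhancement ->
#' feature extraction (built-in handcrafted extractor, or precomputed CSVs)
#' -> serial--harmonic-mean fusion -> MPA feature selection (optional) ->
#' stratified split and classification. Each stage's wall-clock and output
#' summary are recorded in a run manifest; the run is a pure function of
#' (config, seed) apart from the timing fields.
#'
#' @param config nested list as returned by [read_config()], or a path to a
#'   config file. Recognised sections/keys (all optional):
#'   \describe{
#'     \item{data}{`n_images`, `n_classes`, `height`, `width` — synthetic
#'       image generation; or `features_a` / `features_b` CSV paths to skip
#'       the image stages.}
#'     \item{select}{`enabled` (0/1), `iterations`, `population`.}
#'     \item{evaluate}{`classifier`, `ratio`.}
#'   }
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory for stage artifacts (CSV/JSON/PNG).
#' @return list of class `run_manifest`: config echo, seed, per-stage
#'   timings, the selection result (or NULL), the evaluation report, and
#'   paths of written artifacts.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  tic <- function() proc.time()["elapsed"]
  timings <- c()
  artifacts <- character(0)
  seed <- as.integer(seed)

  dat <- config$data
  n_images <- as.integer(dat$n_images %||% 60L)
  n_classes <- as.integer(dat$n_classes %||% 3L)
  hw <- as.integer(dat$height %||% 64L)
  ww <- as.integer(dat$width %||% 64L)

  if (!is.null(dat$features_a)) {
    t0 <- tic()
    Fa <- read_features_csv(dat$features_a, source = "A")
    Fb <- read_features_csv(dat$features_b, source = "B")
    timings["load_features"] <- tic() - t0
  } else {
    # image generation: class shifts lesion darkening and size
    t0 <- tic()
    labels <- sort(rep_len(0:(n_classes - 1L), n_images))
    images <- vector("list", n_images)
    masks <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      cl <- labels[i]
      sp <- lesion_image_spec(
        height = hw, width = ww,
        axes = c(hw / (5 + cl), hw / (7 + cl)),
        darkening = 0.3 + 0.15 * cl,
        irregularity = 0.1 + 0.05 * cl,
        seed = seed * 1000L + i)
      images[[i]] <- make_lesion_image(sp)
    }
    timings["simulate"] <- tic() - t0

    t0 <- tic()
    for (i in seq_len(n_images)) {
      enh <- enhance(images[[i]]$image)
      images[[i]]$image <- enh$image
      masks[[i]] <- enh$mask
    }
    timings["enhance"] <- tic() - t0

    t0 <- tic()
    views <- extract_features(images, masks = masks, labels = labels)
    Fa <- views$Fa; Fb <- views$Fb
    timings["extract"] <- tic() - t0
  }

  t0 <- tic()
  fused <- fuse(Fa, Fb, seed = seed)
  timings["fuse"] <- tic() - t0

  sel <- NULL
  X <- fused$matrix
  sel_cfg <- config$select
  sel_enabled <- is.null(sel_cfg$enabled) || as.numeric(sel_cfg$enabled) != 0
  if (sel_enabled) {
    t0 <- tic()
    mcfg <- mpa_config(
      population_size = as.integer(sel_cfg$population %||% 20L),
      iterations = as.integer(sel_cfg$iterations %||% 50L),
      seed = seed)
    sel <- select_features(X, config = mcfg)
    X <- feature_matrix(X$values[, sel$mask, drop = FALSE],
                        labels = X$labels,
                        column_ids = X$column_ids[sel$mask])
    timings["select"] <- tic() - t0
  }

  t0 <- tic()
  ev_cfg <- config$evaluate
  split <- split_train_test(X, ratio = as.numeric(ev_cfg$ratio %||% 0.5),
                            seed = seed)
  report <- evaluate_classifier(split$train, split$test,
                                classifier = ev_cfg$classifier %||% "cubic_svm",
                                seed = seed)
  timings["evaluate"] <- tic() - t0

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "fused.csv")
    write_features_csv(fused$matrix, p); artifacts <- c(artifacts, p)
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      accuracy = report$accuracy, macro_recall = report$macro_recall,
      macro_precision = report$macro_precision, macro_f1 = report$macro_f1,
      fnr = report$fnr, confusion = report$confusion,
      selected = if (is.null(sel)) NULL else sel$selected_indices),
      p, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, p)
  }

  structure(list(config = config, seed = seed, timings = timings,
                 fused = fused, selection = sel, report = report,
                 artifacts = artifacts),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  fused columns: %d of %d\n",
              length(x$fused$kept_indices), length(x$fused$scores)))
  if (!is.null(x$selection))
    cat(sprintf("  selected features: %d\n", sum(x$selection$mask)))
  cat(sprintf("  accuracy: %.1f%%\n", x$report$accuracy))
  cat("  stage timings (s):\n")
  print(round(x$timings, 2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
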