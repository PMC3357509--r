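#' Classification dataset container
#'
#' Bundles a feature matrix with class labels and the network target
#' encoding. Binary tasks carry 0/1 labels and a single target column;
#' multi-class tasks carry 1-based labels and one-hot target rows.
#'
#' @param features numeric matrix (patterns x features).
#' @param labels class labels: 0/1 (binary) or 1..C (one-hot).
#' @param task `"binary"` or `"one_hot"`.
#' @param name dataset name used in reports.
#' @param normalization optional per-feature `(min, max)` matrix recording a
#'   min-max rescale already applied to `features`.
#' @param n_class number of classes for one-hot encoding; defaults to
#'   `max(labels)`. Needed when a subset does not contain every class.
#' @return an object of class `angn_dataset` with fields `features`,
#'   `labels`, `targets`, `task`, `name`, `normalization`.
#' @export
angn_dataset <- function(features, labels, task = c("binary", "one_hot"),
                         name = "dataset", normalization = NULL,
                         n_class = NULL) {
  task <- match.arg(task)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`features` and `labels` must agree in length", call. = FALSE)
  }
  if (task == "binary") {
    if (!all(labels %in% c(0L, 1L))) {
      stop("binary labels must be 0/1", call. = FALSE)
    }
    targets <- matrix(as.numeric(labels), ncol = 1L)
  } else {
    if (is.null(n_class)) n_class <- max(labels)
    if (n_class < 2L || !all(labels >= 1L) || any(labels > n_class)) {
      stop("one-hot labels must be 1-based class indices", call. = FALSE)
    }
    targets <- matrix(0, nrow = length(labels), ncol = n_class)
    targets[cbind(seq_along(labels), labels)] <- 1
  }
  structure(
    list(features = features, labels = labels, targets = targets,
         task = task, name = name, normalization = normalization),
    class = "angn_dataset"
  )
}

#' @export
print.angn_dataset <- function(x, ...) {
  cat(sprintf("<angn_dataset> %s: %d patterns, %d features, %s task\n",
              x$name, nrow(x$features), ncol(x$features), x$task))
  invisible(x)
}

#' Multiplexer truth table
#'
#' Enumerates every boolean input pattern of a multiplexer with
#' `select_lines` select bits addressing `data_lines = 2^select_lines` data
#' bits. Feature columns are the select bits (most significant first)
#' followed by the data bits; the target is the data bit addressed by the
#' select value. The default 2-select/4-data device yields all 64 patterns
#' over 6 inputs, of which exactly half have output 1.
#'
#' @param select_lines number of select bits.
#' @param data_lines number of data bits; must equal `2^select_lines`.
#' @return an [angn_dataset()] (binary task, named `"mux"`).
#' @examples
#' mux <- generate_mux()
#' nrow(mux$features)  # 64
#' @export
generate_mux <- function(select_lines = 2L, data_lines = 4L) {
  select_lines <- as.integer(select_lines)
  data_lines <- as.integer(data_lines)
  if (data_lines != 2L^select_lines) {
    stop("`data_lines` must equal 2^select_lines", call. = FALSE)
  }
  n_in <- select_lines + data_lines
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n_in))[, n_in:1])
  dimnames(grid) <- list(NULL, c(paste0("s", seq_len(select_lines)),
                                 paste0("d", seq_len(data_lines) - 1L)))
  sel <- grid[, seq_len(select_lines), drop = FALSE]
  # select value: s1 is the most significant bit
  addr <- drop(sel %*% 2^((select_lines - 1L):0))
  data <- grid[, select_lines + seq_len(data_lines), drop = FALSE]
  out <- data[cbind(seq_len(nrow(grid)), addr + 1L)]
  angn_dataset(grid, out, task = "binary", name = "mux")
}

#' Load a delimited classification dataset
#'
#' Reads a comma- or tab-separated file with a header row, numeric feature
#' columns and one class-label column. Class labels are mapped to 1-based
#' indices (in order of first appearance for character labels, sorted order
#' for numeric ones) and one-hot encoded; with two classes labelled 0/1 the
#' task is binary.
#'
#' @param path file path.
#' @param class_column name or index of the label column (default: last).
#' @param normalize if `TRUE`, min-max rescale each feature onto `[0, 1]`.
#' @param name dataset name; defaults to the file name.
#' @param sep field separator, `","` or `"\t"`; guessed from the first line
#'   when `NULL`.
#' @return an [angn_dataset()].
#' @export
load_tabular <- function(path, class_column = NULL, normalize = TRUE,
                         name = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (is.null(class_column)) class_column <- ncol(df)
  if (is.character(class_column)) {
    class_column <- match(class_column, names(df))
    if (is.na(class_column)) stop("class column not found", call. = FALSE)
  }
  raw_labels <- df[[class_column]]
  feats <- df[, -class_column, drop = FALSE]
  for (j in seq_along(feats)) {
    v <- suppressWarnings(as.numeric(feats[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric feature value in column '%s', row %d",
                   names(feats)[j], bad), call. = FALSE)
    }
    feats[[j]] <- v
  }
  features <- as.matrix(feats)
  normalization <- NULL
  if (normalize) {
    rng <- apply(features, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    if (any(span == 0)) {
      stop("constant feature column(s) cannot be min-max normalized: ",
           paste(colnames(features)[span == 0], collapse = ", "),
           call. = FALSE)
    }
    features <- sweep(sweep(features, 2L, rng[1L, ]), 2L, span, "/")
    normalization <- rng
  }
  classes <- if (is.numeric(raw_labels)) sort(unique(raw_labels))
             else unique(raw_labels)
  labels <- match(raw_labels, classes)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  if (length(classes) == 2L && is.numeric(raw_labels) &&
      all(raw_labels %in% c(0, 1))) {
    angn_dataset(features, raw_labels, task = "binary", name = name,
                 normalization = normalization)
  } else {
    ds <- angn_dataset(features, labels, task = "one_hot", name = name,
                       normalization = normalization)
    ds$class_names <- as.character(classes)
    ds
  }
}

#' Write a dataset as delimited text
#'
#' Features plus a final `class` column, comma-separated with a header;
#' numbers at full precision so a write/load round trip is exact.
#'
#' @param ds an [angn_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$features)
  df$class <- ds$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(v) {
    sprintf("%.17g", as.numeric(v))
  }), sep = ",")), con)
  invisible(path)
}

#' Split a dataset into training and validation sets
#'
#' Produces a seeded, disjoint, exhaustive split. In stratified mode the
#' training quota is computed per class (largest-fractional-part rounding
#' so the overall training size equals `round(n * train_fraction)`), which
#' guarantees every class appears on both sides for reasonable fractions —
#' e.g. the 64-pattern multiplexer set at `58/64` yields 58 training and 6
#' validation patterns with both output classes among the 6.
#'
#' @param ds an [angn_dataset()].
#' @param train_fraction fraction of patterns used for training, in (0, 1).
#' @param stratified balance classes across the split (default `TRUE`).
#' @param seed integer seed for the split draw.
#' @return a list with `train` and `validation` datasets and the drawn
#'   `train_idx`.
#' @export
split_dataset <- function(ds, train_fraction, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(ds$features)
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop("split leaves an empty training or validation set", call. = FALSE)
  }
  idx <- with_seed(seed, {
    if (stratified) {
      by_class <- split(seq_len(n), ds$labels)
      quota <- vapply(by_class, length, 1L) * train_fraction
      base <- floor(quota)
      extra <- n_train - sum(base)
      if (extra > 0) {
        ord <- order(quota - base, decreasing = TRUE)
        base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
      }
      if (any(base < 1L) || any(base >= vapply(by_class, length, 1L) + 1L)) {
        stop("a class has too few members for a stratified split",
             call. = FALSE)
      }
      unlist(mapply(function(members, q) {
        if (q > length(members)) {
          stop("a class has too few members for a stratified split",
               call. = FALSE)
        }
        sample(members, q)
      }, by_class, base, SIMPLIFY = FALSE), use.names = FALSE)
    } else {
      sample(n, n_train)
    }
  })
  idx <- sort(idx)
  subset_ds <- function(rows, suffix) {
    out <- angn_dataset(ds$features[rows, , drop = FALSE], ds$labels[rows],
                        task = ds$task, name = paste0(ds$name, suffix),
                        normalization = ds$normalization,
                        n_class = if (ds$task == "one_hot") ncol(ds$targets))
    out$class_names <- ds$class_names
    out
  }
  list(train = subset_ds(idx, "_train"),
       validation = subset_ds(setdiff(seq_len(n), idx), "_val"),
       train_idx = idx)
}
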