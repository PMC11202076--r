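#' Write a classifier head archive
#'
#' Two on-disk formats are supported. `hdf5` is the canonical container:
#' datasets `weights` (N x M), `biases`, `labels`, scalars `n_original`,
#' `version` and `method`; doubles are stored natively so the round trip is
#' bit-exact. `csv_pair` is a human-inspectable alternative: a weights CSV
#' (first column = class label, header row = feature ids) plus a JSON
#' sidecar `<path>.meta.json` holding biases, `n_original`, `method` and
#' the format version; numbers are printed with 17 significant digits,
#' which round-trips IEEE doubles exactly.
#'
#' @param head a [classifier_head()].
#' @param path output file path.
#' @param format `"hdf5"` or `"csv_pair"`.
#' @param force overwrite an existing file? Defaults to `FALSE` (error).
#' @return `path`, invisibly.
#' @export
write_head <- function(head, path, format = c("hdf5", "csv_pair"),
                       force = FALSE) {
  format <- match.arg(format)
  validate_head(head)
  if (file.exists(path) && !force)
    stop(sprintf("'%s' exists; use force = TRUE to overwrite", path))
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5write(head$weights, path, "weights")
    rhdf5::h5write(head$biases, path, "biases")
    rhdf5::h5write(head$labels, path, "labels")
    rhdf5::h5write(head$n_original, path, "n_original")
    rhdf5::h5write(HEAD_FORMAT_VERSION, path, "version")
    rhdf5::h5write(attr(head, "method"), path, "method")
  } else {
    m <- ncol(head$weights)
    tab <- data.frame(label = head$labels,
                      apply(head$weights, 2, fmt17),
                      check.names = FALSE)
    colnames(tab) <- c("label", paste0("f", seq_len(m)))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    meta <- list(version = HEAD_FORMAT_VERSION,
                 n_original = head$n_original,
                 method = attr(head, "method"),
                 biases = fmt17(head$biases))
    jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE)
  }
  invisible(path)
}

HEAD_FORMAT_VERSION <- "imprintkit-1"

fmt17 <- function(x) sprintf("%.17g", x)
meta_path <- function(path) paste0(path, ".meta.json")

#' Read a classifier head archive
#'
#' Inverse of [write_head()]; the result passes [validate_head()]. For
#' `csv_pair`, a row with the wrong number of fields is reported with its
#' row number, and a sidecar missing `n_original` is an error — there is no
#' silent default.
#'
#' @param path archive path (for `csv_pair`, the weights CSV; the
#'   `.meta.json` sidecar is located automatically).
#' @param format `"hdf5"` or `"csv_pair"`.
#' @return a [classifier_head()].
#' @export
read_head <- function(path, format = c("hdf5", "csv_pair")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (format == "hdf5") {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    w <- rhdf5::h5read(path, "weights")
    head <- classifier_head(
      w,
      as.double(rhdf5::h5read(path, "biases")),
      as.character(rhdf5::h5read(path, "labels")),
      n_original = as.integer(rhdf5::h5read(path, "n_original")),
      method = as.character(rhdf5::h5read(path, "method")))
  } else {
    lines <- readLines(path)
    if (length(lines) < 2) stop(sprintf("'%s': no data rows", path))
    fields <- strsplit(lines, ",", fixed = TRUE)
    m <- length(fields[[1]]) - 1
    for (i in seq_along(fields)[-1]) {
      if (length(fields[[i]]) != m + 1)
        stop(sprintf("'%s': row %d has %d fields, expected %d",
                     path, i, length(fields[[i]]), m + 1))
    }
    labels <- vapply(fields[-1], `[[`, character(1), 1)
    w <- do.call(rbind, lapply(fields[-1], function(f) as.double(f[-1])))
    if (anyNA(w)) stop(sprintf("'%s': non-numeric weight value", path))
    mp <- meta_path(path)
    if (!file.exists(mp)) stop(sprintf("missing sidecar '%s'", mp))
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (is.null(meta$n_original))
      stop(sprintf("'%s': n_original missing (no silent default)", mp))
    head <- classifier_head(w, as.double(meta$biases), labels,
                            n_original = as.integer(meta$n_original),
                            method = if (is.null(meta$method)) "none"
                                     else meta$method)
  }
  head
}

#' Write/read a labeled activation set as CSV
#'
#' Rows are items; columns are the features, plus a `label` column and an
#' `is_original` flag. Values use 17 significant digits.
#'
#' @param set an [activation_set()].
#' @param path CSV path.
#' @param force overwrite an existing file?
#' @return `path` invisibly (write); an `activation_set` (read).
#' @export
write_activations <- function(set, path, force = FALSE) {
  stopifnot(inherits(set, "activation_set"))
  if (file.exists(path) && !force)
    stop(sprintf("'%s' exists; use force = TRUE to overwrite", path))
  tab <- data.frame(label = set$labels, is_original = set$is_original,
                    apply(set$x, 2, fmt17), check.names = FALSE)
  colnames(tab) <- c("label", "is_original", paste0("f", seq_len(ncol(set$x))))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activations
#' @export
read_activations <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  feat <- setdiff(colnames(tab), c("label", "is_original"))
  activation_set(as.matrix(tab[, feat, drop = FALSE]),
                 as.character(tab$label),
                 if ("is_original" %in% colnames(tab)) tab$is_original
                 else rep(TRUE, nrow(tab)))
}

#' Write an evaluation report as TSV and/or JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path; extension `.json` selects the JSON mirror,
#'   anything else a TSV table (metric, value, numerator, denominator).
#' @param force overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop(sprintf("'%s' exists; use force = TRUE to overwrite", path))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(original_top1 = report$original_top1,
           interference_fraction = report$interference_fraction,
           per_new_class_top1 = as.list(report$per_new_class_top1),
           counts = list(original_total = report$counts$original_total,
                         original_correct = report$counts$original_correct,
                         interfered = report$counts$interfered)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A declarative description of a `simulate` run: imprinting `method`,
#' `shots`, `seed`, `n_new_classes`, `eval_per_class`, and a `synthetic`
#' block of [synthetic_spec()] fields. Unknown keys are rejected so typos
#' never silently fall back to defaults.
#'
#' @param path config path (`.yaml`/`.yml` or `.json`).
#' @return a named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  allowed <- c("method", "shots", "seed", "n_new_classes", "eval_per_class",
               "synthetic", "output")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  spec_allowed <- c("n_classes", "m_features", "activation_shape",
                    "weight_mean", "weight_sd", "noise_sd", "bias_sd", "seed")
  unknown <- setdiff(names(cfg$synthetic), spec_allowed)
  if (length(unknown))
    stop(sprintf("unknown synthetic key(s): %s", paste(unknown, collapse = ", ")))
  defaults <- list(method = "done4", shots = 1, seed = 1,
                   n_new_classes = 8, eval_per_class = 25,
                   synthetic = list())
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Execute a run configuration
#' @param cfg a [read_run_config()] result.
#' @return the `evaluation_report` from [run_experiment()].
#' @export
run_config_experiment <- function(cfg) {
  spec <- do.call(synthetic_spec, cfg$synthetic)
  run_experiment(spec, method = cfg$method, n_new_classes = cfg$n_new_classes,
                 shots = cfg$shots, eval_per_class = cfg$eval_per_class,
                 seed = cfg$seed)
}
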