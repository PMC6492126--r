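#' Write an (incomplete) dataset to CSV
#'
#' UTF-8 comma-separated file with header; missing covariate values are
#' written as empty fields.
#'
#' @param data data frame.
#' @param path output file.
#' @param include_r whether to keep the response-indicator column `r` (it
#'   is derivable from the missingness pattern).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, include_r = FALSE) {
  if (!include_r) data$r <- NULL
  utils::write.csv(data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read an (incomplete) dataset from CSV
#'
#' Reads a header CSV, types the outcome as 0/1 integer and the incomplete
#' covariate as a factor, detects missingness from empty fields or the
#' configured sentinels, and derives the response indicator.
#'
#' @param path CSV file with a header row.
#' @param x_var name of the incomplete covariate column.
#' @param y_var name of the binary outcome column.
#' @param covariates optional further (fully observed) categorical
#'   columns to keep and factor.
#' @param levels optional declared level set for the covariate; values
#'   outside it are an error.
#' @param na_strings field values treated as missing.
#' @return A typed data frame with a derived integer column `r`.
#' @export
read_cohort <- function(path, x_var = "x", y_var = "y", covariates = NULL,
                        levels = NULL, na_strings = c("", "NA")) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c(x_var, y_var, covariates)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("column(s) not found in ", path, ": ", paste(absent, collapse = ", "))
  out <- raw[need]
  xs <- out[[x_var]]
  xs[xs %in% na_strings] <- NA
  if (!is.null(levels)) {
    bad <- which(!is.na(xs) & !xs %in% levels)
    if (length(bad))
      stop("unknown level(s) of ", x_var, " in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), ": ",
           paste(unique(xs[bad]), collapse = ", "))
    out[[x_var]] <- factor(xs, levels = levels)
  } else {
    out[[x_var]] <- factor(xs)
  }
  ys <- out[[y_var]]
  if (any(ys %in% na_strings) || anyNA(ys))
    stop("outcome ", y_var, " has missing values (row ",
         which(ys %in% na_strings | is.na(ys))[1L], "); the outcome must be ",
         "fully observed")
  if (!all(ys %in% c("0", "1")))
    stop("outcome ", y_var, " must be coded 0/1")
  out[[y_var]] <- as.integer(ys)
  for (v in covariates) {
    if (any(out[[v]] %in% na_strings))
      stop("covariate ", v, " has missing values; only ", x_var,
           " may be incomplete")
    out[[v]] <- factor(out[[v]])
  }
  out$r <- as.integer(!is.na(out[[x_var]]))
  out
}

#' Read a population reference from a file or inline specification
#'
#' Accepts either a named numeric vector / named list of proportions
#' (fixed mode unless `n_ex` is given), or a path to a YAML/JSON file with
#' fields `proportions` (map of level to proportion), optional `mode`
#' (`fixed`/`estimated`) and `n_ex`.
#'
#' @param x inline proportions or a file path.
#' @param n_ex external sample size (switches inline specs to estimated
#'   mode).
#' @return A [population_reference()].
#' @export
read_reference <- function(x, n_ex = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    spec <- yaml::read_yaml(x)
    if (is.null(spec$proportions))
      stop("reference file ", x, " must contain a 'proportions' map")
    mode <- spec$mode %||% if (is.null(spec$n_ex)) "fixed" else "estimated"
    if (identical(mode, "estimated") && is.null(spec$n_ex))
      stop("estimated-mode reference requires n_ex")
    return(population_reference(unlist(spec$proportions), mode = mode,
                                n_ex = spec$n_ex))
  }
  if (is.numeric(x) || is.list(x)) {
    mode <- if (is.null(n_ex)) "fixed" else "estimated"
    return(population_reference(unlist(x), mode = mode, n_ex = n_ex))
  }
  stop("cannot interpret the reference specification (not a file or a ",
       "named proportion vector)")
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file.
#' @param required character vector of keys that must be present.
#' @return Named list.
#' @export
read_config <- function(path, required = character()) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare keys n/y as booleans; restore them
  nm <- names(cfg)
  nm[nm == "FALSE"] <- "n"
  nm[nm == "TRUE"] <- "y"
  names(cfg) <- nm
  absent <- setdiff(required, names(cfg))
  if (length(absent))
    stop("missing configuration key(s): ", paste(absent, collapse = ", "))
  cfg
}

#' Build a reproducibility manifest for a run
#'
#' Records the command, a hash of the full (defaults-echoed)
#' configuration, the master seed, the package version, a timestamp and
#' the inventory of output files, so that a run is self-describing and
#' byte-reproducible from its manifest.
#'
#' @param command name of the command executed.
#' @param config the full configuration (after defaults were applied).
#' @param seed master seed used.
#' @param outputs character vector of files written.
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(command, config, seed, outputs = character()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  h <- unname(tools::md5sum(tmp)); unlink(tmp)
  structure(list(command = command, config = config, config_hash = h,
                 seed = seed,
                 package_version = as.character(utils::packageVersion("calmi")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 outputs = outputs),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
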