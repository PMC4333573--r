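#' Read one session of region-averaged BOLD time series
#'
#' Reads a whitespace- or comma-delimited numeric table holding the BOLD time
#' series of all cortical regions for one scanning session (the
#' \code{subXblockY.txt} dialect: one file per subject and run). The table is
#' returned in frames x regions orientation; a regions x frames table is
#' transposed automatically when exactly one dimension equals
#' \code{n_regions}.
#'
#' When both dimensions equal \code{n_regions} the orientation is ambiguous
#' and the function refuses to guess unless \code{orientation} is given:
#' silent transposition is the worst failure mode for downstream phase
#' statistics.
#'
#' @param path Path to the delimited numeric text file.
#' @param n_regions Expected number of regions (66 for the study data).
#' @param sampling_period Sampling period in seconds (TR; 2 for the study
#'   data).
#' @param region_labels Optional character vector of region labels; defaults
#'   to \code{R1..Rn}.
#' @param orientation One of \code{"auto"}, \code{"frames_by_regions"},
#'   \code{"regions_by_frames"}. Only consulted when the table is square.
#' @return A list with elements \code{subject}, \code{run}, \code{samples}
#'   (frames x regions numeric matrix), \code{sampling_period},
#'   \code{region_labels}.
#' @export
read_session_table <- function(path, n_regions = 66, sampling_period = 2,
                               region_labels = NULL,
                               orientation = c("auto", "frames_by_regions",
                                               "regions_by_frames")) {
  orientation <- match.arg(orientation)
  m <- read_numeric_table(path)
  if (nrow(m) == n_regions && ncol(m) == n_regions) {
    if (orientation == "auto") {
      stop("table is ", n_regions, "x", n_regions,
           ": orientation is ambiguous, pass `orientation` explicitly")
    }
    if (orientation == "regions_by_frames") m <- t(m)
  } else if (ncol(m) == n_regions) {
    # already frames x regions
  } else if (nrow(m) == n_regions) {
    m <- t(m)
  } else {
    stop("region count mismatch: table is ", nrow(m), "x", ncol(m),
         ", expected one dimension equal to ", n_regions)
  }
  if (nrow(m) < 30) stop("fewer than 30 frames in ", path)
  if (!all(is.finite(m))) stop("non-finite samples in ", path)
  ids <- parse_session_id(basename(path))
  if (is.null(region_labels)) {
    region_labels <- paste0("R", seq_len(ncol(m)))
  }
  stopifnot(length(region_labels) == ncol(m))
  dimnames(m) <- NULL
  colnames(m) <- region_labels
  list(subject = ids$subject, run = ids$run, samples = m,
       sampling_period = sampling_period, region_labels = region_labels)
}

#' Read a directory of session files
#'
#' @param dir Directory containing \code{subXblockY.txt} files.
#' @param pattern Filename regular expression.
#' @inheritParams read_session_table
#' @return A list of session records (see \code{\link{read_session_table}}).
#' @export
read_sessions <- function(dir, pattern = "^sub[0-9]+block[0-9]+\\.txt$",
                          n_regions = 66, sampling_period = 2,
                          region_labels = NULL) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no session files matching '", pattern,
                               "' in ", dir)
  lapply(files, read_session_table, n_regions = n_regions,
         sampling_period = sampling_period, region_labels = region_labels)
}

#' Write a session in the plain-text session dialect
#'
#' @param session A session record (frames x regions \code{samples}).
#' @param path Output file path; the conventional name is
#'   \code{sub<subject>block<run>.txt}.
#' @param digits Significant digits to keep.
#' @export
write_session_table <- function(session, path, digits = 12) {
  utils::write.table(format(session$samples, digits = digits,
                            scientific = TRUE, trim = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a weighted structural connectome matrix
#'
#' Reads a delimited numeric n x n matrix of nonnegative coupling weights
#' (e.g. tractography fiber densities normalized per target region). The
#' matrix need not be symmetric. Self-connections are not allowed: a nonzero
#' diagonal is zeroed with a warning.
#'
#' @param path Path to the delimited matrix file.
#' @param region_labels Optional region labels (length n).
#' @return An object of class \code{connectome}: a list with \code{weights}
#'   (n x n matrix, zero diagonal) and \code{region_labels}.
#' @export
read_connectome <- function(path, region_labels = NULL) {
  m <- read_numeric_table(path)
  as_connectome(m, region_labels = region_labels)
}

#' Construct a connectome object from a weight matrix
#'
#' @param weights Square nonnegative numeric matrix.
#' @param region_labels Optional labels.
#' @return A \code{connectome} object.
#' @export
as_connectome <- function(weights, region_labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome matrix must be square, got ",
         nrow(weights), "x", ncol(weights))
  }
  if (any(!is.finite(weights))) stop("non-finite connectome weights")
  if (any(weights < 0)) stop("negative connectome weights are not allowed")
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to zero (no self-connections)")
    diag(weights) <- 0
  }
  n <- nrow(weights)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  stopifnot(length(region_labels) == n)
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  off <- w[row(w) != col(w)]
  cat("Weighted connectome: ", nrow(w), " regions, density ",
      signif(mean(off > 0), 3), ", mean weight ",
      signif(mean(off[off > 0]), 3), "\n", sep = "")
  invisible(x)
}

#' Read region labels, one per line
#'
#' @param path Path to a plain-text file with one region label per line.
#' @return Character vector of labels.
#' @export
read_region_labels <- function(path) {
  labs <- readLines(path, warn = FALSE)
  labs <- trimws(labs)
  labs[nzchar(labs)]
}

#' Read binary reference network maps
#'
#' Reads resting-state network reference maps as a delimited table of 0/1
#' values, one column per map, rows in region order (a header row of map
#' names is accepted).
#'
#' @param path Path to the CSV/TSV file.
#' @return Numeric matrix (regions x maps) with entries in \{0, 1\}.
#' @export
read_reference_maps <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,\t ]+")[[1]]))))
  m <- as.matrix(utils::read.table(path, header = has_header,
                                   sep = sniff_sep(first)))
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1))) stop("reference maps must be binary 0/1")
  m
}

# -- internal helpers ---------------------------------------------------------

read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  m <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE, sep = sniff_sep(first))),
    error = function(e) stop("could not parse numeric table ", path, ": ",
                             conditionMessage(e)))
  if (!is.numeric(m)) stop("non-numeric content in ", path)
  dimnames(m) <- NULL
  m
}

sniff_sep <- function(line) {
  if (grepl(",", line)) "," else ""
}

parse_session_id <- function(filename) {
  m <- regmatches(filename,
                  regexec("sub([0-9]+)block([0-9]+)", filename))[[1]]
  if (length(m) == 3) {
    list(subject = as.integer(m[2]), run = as.integer(m[3]))
  } else {
    list(subject = NA_integer_, run = NA_integer_)
  }
}
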