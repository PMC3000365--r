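#' @keywords internal
"_PACKAGE"

TISSUES <- c("tail", "heart", "lung", "spleen", "liver", "cortex",
             "striatum", "other")

FLANK_BP <- 86    # total flanking sequence around the CAG tract, bp
BP_PER_REPEAT <- 3

#' Construct a fragment-analysis trace
#'
#' A trace is a sampled electropherogram: fragment size in base pairs versus
#' fluorescence intensity, carrying the sample's metadata (mouse identifier,
#' tissue, age in weeks).
#'
#' @param size_bp Numeric vector of fragment sizes in bp, strictly increasing.
#' @param intensity Numeric vector of non-negative fluorescence intensities,
#'   the same length as `size_bp`.
#' @param mouse Mouse identifier (string).
#' @param tissue One of `"tail"`, `"heart"`, `"lung"`, `"spleen"`, `"liver"`,
#'   `"cortex"`, `"striatum"`, `"other"`.
#' @param age_weeks Age at sampling, in weeks (positive).
#' @return An object of class `"cag_trace"`: a list with elements `size_bp`,
#'   `intensity` and `meta`.
#' @examples
#' tr <- cag_trace(seq(430, 456, by = 0.5),
#'                 dnorm(seq(430, 456, by = 0.5), 443, 6))
#' tr
#' @export
cag_trace <- function(size_bp, intensity, mouse = NA_character_,
                      tissue = "other", age_weeks = NA_real_) {
  size_bp <- as.numeric(size_bp)
  intensity <- as.numeric(intensity)
  if (length(size_bp) != length(intensity))
    stop("size_bp and intensity must have the same length")
  if (length(size_bp) < 3L)
    stop("a trace needs at least 3 points")
  if (anyNA(size_bp) || anyNA(intensity) ||
      any(!is.finite(size_bp)) || any(!is.finite(intensity)))
    stop("non-finite values in trace")
  d <- diff(size_bp)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop(sprintf("sizes not increasing at row %d", bad))
  }
  if (any(intensity < 0)) {
    bad <- which(intensity < 0)[1L]
    stop(sprintf("negative intensity at row %d", bad))
  }
  tissue <- match.arg(tissue, TISSUES)
  structure(
    list(size_bp = size_bp, intensity = intensity,
         meta = list(mouse = as.character(mouse), tissue = tissue,
                     age_weeks = as.numeric(age_weeks))),
    class = "cag_trace")
}

#' @export
print.cag_trace <- function(x, ...) {
  cat(sprintf("<cag_trace> %d points, %.1f-%.1f bp\n",
              length(x$size_bp), min(x$size_bp), max(x$size_bp)))
  m <- x$meta
  cat(sprintf("  mouse: %s  tissue: %s  age: %s weeks\n",
              m$mouse, m$tissue, format(m$age_weeks)))
  cat(sprintf("  total area: %.4g intensity*bp\n", trace_area(x)))
  invisible(x)
}

#' @export
plot.cag_trace <- function(x, ...) {
  graphics::plot(x$size_bp, x$intensity, type = "l",
                 xlab = "fragment size (bp)", ylab = "intensity", ...)
  invisible(x)
}

#' Trapezoidal area of a trace
#'
#' @param trace A [cag_trace()].
#' @return Total area (intensity times bp) under the trace, by the
#'   trapezoidal rule.
#' @export
trace_area <- function(trace) {
  stopifnot(inherits(trace, "cag_trace"))
  trapz(trace$size_bp, trace$intensity)
}

trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Convert a fragment size in bp to CAG repeat units
#'
#' The CAG tract is flanked by 86 bp of constant sequence, so a fragment of
#' mean size \eqn{\mu_m} bp carries \eqn{\mu_t = (\mu_m - 86)/3} repeats.
#'
#' @param mean_size_bp Fragment size(s) in bp, each at least 86.
#' @return Repeat count(s), possibly fractional for fitted means.
#' @examples
#' repeats_from_size(443)  # 119
#' @export
repeats_from_size <- function(mean_size_bp) {
  if (any(mean_size_bp < FLANK_BP))
    stop("fragment smaller than the 86 bp flank")
  (mean_size_bp - FLANK_BP) / BP_PER_REPEAT
}

#' Convert CAG repeat units to fragment size in bp
#'
#' Inverse of [repeats_from_size()]: size = 86 + 3 * repeats.
#'
#' @param repeats Repeat count(s), non-negative.
#' @return Fragment size(s) in bp.
#' @export
size_from_repeats <- function(repeats) {
  if (any(repeats < 0)) stop("negative repeat count")
  FLANK_BP + BP_PER_REPEAT * repeats
}

#' Read a trace from delimited text
#'
#' The file has two columns, `size_bp` and `intensity`, tab- or
#' comma-delimited (auto-detected), with an optional header and
#' `#`-prefixed comment lines. Metadata may live in a flat key-value sidecar
#' file `<path>.meta` with keys `mouse`, `tissue`, `age_weeks`.
#'
#' @param path Path to the trace file.
#' @return A [cag_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trace file: ", path)
  sep <- if (grepl(",", lines[[1L]])) "," else "\t"
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  has_header <- suppressWarnings(anyNA(as.numeric(first)))
  dat <- utils::read.table(text = lines, sep = sep, header = has_header,
                           strip.white = TRUE)
  if (ncol(dat) < 2L) stop("trace file must have two columns: ", path)
  size_bp <- suppressWarnings(as.numeric(dat[[1L]]))
  intensity <- suppressWarnings(as.numeric(dat[[2L]]))
  bad <- which(!is.finite(size_bp) | !is.finite(intensity))
  if (length(bad))
    stop(sprintf("non-finite value at row %d of %s", bad[1L], path))
  meta <- read_meta_sidecar(paste0(path, ".meta"))
  cag_trace(size_bp, intensity, mouse = meta$mouse, tissue = meta$tissue,
            age_weeks = meta$age_weeks)
}

read_meta_sidecar <- function(path) {
  meta <- list(mouse = NA_character_, tissue = "other", age_weeks = NA_real_)
  if (!file.exists(path)) return(meta)
  kv <- read_keyvalue(path)
  if (!is.null(kv$mouse)) meta$mouse <- kv$mouse
  if (!is.null(kv$tissue)) meta$tissue <- kv$tissue
  if (!is.null(kv$age_weeks)) meta$age_weeks <- as.numeric(kv$age_weeks)
  meta
}

#' Write a trace to delimited text
#'
#' Writes a tab-delimited file with a `size_bp`/`intensity` header and, when
#' metadata is present, a `<path>.meta` key-value sidecar.
#'
#' @param trace A [cag_trace()].
#' @param path Output file path.
#' @param digits Significant digits retained in the text representation.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, digits = 10) {
  stopifnot(inherits(trace, "cag_trace"))
  df <- data.frame(size_bp = signif(trace$size_bp, digits),
                   intensity = signif(trace$intensity, digits))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  m <- trace$meta
  if (!is.na(m$mouse) || !is.na(m$age_weeks) || !identical(m$tissue, "other")) {
    write_keyvalue(list(mouse = m$mouse, tissue = m$tissue,
                        age_weeks = m$age_weeks), paste0(path, ".meta"))
  }
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) >= 2L)
      out[[trimws(kv[[1L]])]] <- trimws(paste(kv[-1L], collapse = "\t"))
  }
  out
}

write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k) paste(k, format(x[[k]]), sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Optional constant-baseline subtraction
#'
#' Subtracts the minimum intensity in the trace from every point. Traces are
#' assumed to arrive baseline-subtracted, so this is off by default in all
#' fitting entry points.
#'
#' @param trace A [cag_trace()].
#' @return The baseline-subtracted trace.
#' @export
subtract_baseline <- function(trace) {
  trace$intensity <- trace$intensity - min(trace$intensity)
  trace
}

# restore the global RNG stream afterwards so seeded package routines do not
# perturb user code
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
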