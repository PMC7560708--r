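#' @title OpenBabel backend
#' @description Internal helpers that shuttle molecules through the
#'   `obabel` command-line tool. All conversions are batched: one process
#'   call converts an arbitrary number of records, each tagged with an
#'   integer title so failed records (empty output) can be mapped back to
#'   their inputs. `-e` keeps obabel going past unparsable records.
#' @name openbabel-backend
#' @keywords internal
NULL

.ob_cache <- new.env(parent = emptyenv())

ob_path <- function() {
  if (!is.null(.ob_cache$path)) return(.ob_cache$path)
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable (OpenBabel >= 3.0) was not found on the PATH. ",
         "samcliff requires OpenBabel for SMILES parsing and canonicalization.",
         call. = FALSE)
  }
  .ob_cache$path <- unname(p)
  .ob_cache$path
}

# Run obabel over `input` text, returning raw stdout lines.
ob_run <- function(input, args) {
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(input, infile)
  status <- suppressWarnings(system2(
    ob_path(), c(shQuote(infile), args, "-O", shQuote(outfile), "-e"),
    stdout = FALSE, stderr = FALSE
  ))
  if (!file.exists(outfile)) return(character(0))
  readLines(outfile, warn = FALSE)
}

# Parse "smiles\ttitle" output lines into a character vector indexed by the
# integer titles 1..n; records obabel dropped or emptied become NA.
.ob_collect_smiles <- function(lines, n) {
  out <- rep(NA_character_, n)
  if (!length(lines)) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    smi <- trimws(p[[1L]])
    idx <- suppressWarnings(as.integer(trimws(p[[2L]])))
    if (!is.na(idx) && idx >= 1L && idx <= n && nzchar(smi)) out[idx] <- smi
  }
  out
}

#' Convert SMILES strings to canonical SMILES (batch).
#' @param smiles character vector.
#' @param extra extra obabel arguments (e.g. "--neutralize", "-d").
#' @return character vector, NA where parsing failed.
#' @keywords internal
ob_can_from_smiles <- function(smiles, extra = character(0)) {
  n <- length(smiles)
  if (!n) return(character(0))
  input <- paste(smiles, seq_len(n))
  lines <- ob_run(input, c("-ismi", "-ocan", extra))
  .ob_collect_smiles(lines, n)
}

#' Convert SMILES to V2000 molblocks (batch), hydrogens deleted.
#' @return list of character vectors (molblock lines), NULL where failed.
#' @keywords internal
ob_sdf_from_smiles <- function(smiles, extra = character(0)) {
  n <- length(smiles)
  out <- vector("list", n)
  if (!n) return(out)
  input <- paste(smiles, seq_len(n))
  lines <- ob_run(input, c("-ismi", "-osdf", "-d", extra))
  blocks <- split_sdf(lines)
  for (b in blocks) {
    idx <- suppressWarnings(as.integer(trimws(b[[1L]])))
    if (!is.na(idx) && idx >= 1L && idx <= n && length(b) > 4L) out[[idx]] <- b
  }
  out
}

#' Convert V2000 molblocks (titled with their index) to canonical SMILES.
#' @param blocks character vector: concatenated SDF text lines.
#' @param n number of records submitted.
#' @keywords internal
ob_can_from_sdf <- function(blocks, n) {
  if (!n) return(character(0))
  lines <- ob_run(blocks, c("-isdf", "-ocan"))
  .ob_collect_smiles(lines, n)
}

# Split concatenated SDF lines into per-record character vectors (without the
# "$$$$" terminators).
split_sdf <- function(lines) {
  if (!length(lines)) return(list())
  ends <- which(lines == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}
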