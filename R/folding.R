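#' Folding backend in use
#'
#' Two interchangeable backends provide minimum-free-energy folding:
#' `"vienna"` shells out to the ViennaRNA command line tools (`RNAduplex`
#' for two-strand hybridisation, `RNAfold` for single-sequence structures;
#' nearest-neighbour parameters at 37 C), `"builtin"` is a bundled
#' dynamic program (stacking-aware duplex alignment and a weighted
#' Nussinov fold) kept deliberately simple but calibrated so that a
#' near-perfect duplex of 16+ bp scores well below -14 kcal/mol and
#' unpairable sequence scores ~0. Absolute energies differ between
#' backends; all downstream cutoffs are percentile-based and therefore
#' insensitive to monotone rescaling, but the duplex gate is a config
#' value for the same reason.
#'
#' @param backend `"auto"`, `"vienna"` or `"builtin"`.
#' @return the resolved backend name.
#' @export
fold_backend <- function(backend = getOption("mirscout.fold_backend", "auto")) {
  if (is.null(backend) || backend == "auto") {
    ok <- nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAduplex"))
    return(if (ok) "vienna" else "builtin")
  }
  match.arg(backend, c("vienna", "builtin"))
}

to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

parse_vienna_energy <- function(line) {
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", line))
}

#' Cofold two arm sequences into their minimum-free-energy duplex
#'
#' Computes the intermolecular hybridisation of two arm-sized sequences
#' (T is treated as U). Returns, per pair of inputs, the duplex MFE, the
#' base-pair index pairs between strand A and strand B, and the number of
#' unpaired nucleotides outside the outermost pair at each of the four
#' strand ends (`a5`, `a3`, `b5`, `b3`) -- the quantities the 3' overhang
#' score is built from.
#'
#' @param a,b character vectors of equal length with the two strands.
#' @param backend folding backend, see [fold_backend()].
#' @return a list of `duplex_fold` objects (`mfe`, `pairs` (two-column
#'   matrix of 1-based positions), `unpaired` (named a5/a3/b5/b3)).
#' @export
fold_duplex <- function(a, b, backend = NULL) {
  stopifnot(length(a) == length(b))
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty sequence in fold_duplex")
  backend <- fold_backend(backend %||% getOption("mirscout.fold_backend", "auto"))
  if (backend == "vienna") {
    inp <- as.vector(rbind(to_rna(a), to_rna(b)))
    out <- system2("RNAduplex", input = inp, stdout = TRUE, stderr = FALSE)
    out <- out[!grepl("^>", out) & nzchar(out)]
    if (length(out) != length(a)) stop("unexpected RNAduplex output")
    res <- mapply(parse_duplex_line, out, nchar(a), nchar(b),
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else {
    res <- mapply(function(x, y) {
      r <- duplex_fold_cpp(to_rna(x), to_rna(y))
      make_duplex_fold(r$mfe, r$pairs, nchar(x), nchar(y))
    }, a, b, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_duplex_fold <- function(mfe, pairs, la, lb) {
  if (is.null(dim(pairs)) || nrow(pairs) == 0L) {
    unp <- c(a5 = 0L, a3 = 0L, b5 = 0L, b3 = 0L)
    return(structure(list(mfe = 0, pairs = matrix(integer(), 0, 2),
                          unpaired = unp), class = "duplex_fold"))
  }
  unp <- c(a5 = min(pairs[, 1]) - 1L, a3 = la - max(pairs[, 1]),
           b5 = min(pairs[, 2]) - 1L, b3 = lb - max(pairs[, 2]))
  structure(list(mfe = mfe, pairs = pairs, unpaired = unp),
            class = "duplex_fold")
}

parse_duplex_line <- function(line, la, lb) {
  m <- regmatches(line, regexec(
    "^(\\S+)\\s+(\\d+),(\\d+)\\s*:\\s*(\\d+),(\\d+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)",
    line))[[1]]
  if (length(m) == 0L) stop("cannot parse RNAduplex line: ", line)
  mfe <- as.numeric(m[7])
  if (mfe >= 0) return(make_duplex_fold(0, matrix(integer(), 0, 2), la, lb))
  halves <- strsplit(m[2], "&", fixed = TRUE)[[1]]
  sa <- strsplit(halves[1], "")[[1]]; sb <- strsplit(halves[2], "")[[1]]
  pa <- which(sa == "(") + as.integer(m[3]) - 1L
  pb <- which(sb == ")") + as.integer(m[5]) - 1L
  if (length(pa) != length(pb)) stop("unbalanced RNAduplex structure: ", line)
  pairs <- cbind(pa, rev(pb))
  make_duplex_fold(mfe, pairs, la, lb)
}

#' @export
print.duplex_fold <- function(x, ...) {
  cat(sprintf("duplex_fold: mfe %.2f kcal/mol, %d pairs, unpaired %s\n",
              x$mfe, nrow(x$pairs),
              paste(names(x$unpaired), x$unpaired, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Fold single sequences into their MFE secondary structure
#'
#' @param seqs character vector of sequences (DNA accepted, transcribed to
#'   RNA internally), typically the extended precursor interval.
#' @param backend folding backend, see [fold_backend()].
#' @return data.frame with columns `mfe` (kcal/mol) and `structure`
#'   (dot-bracket, same length as input).
#' @export
fold_hairpin <- function(seqs, backend = NULL) {
  if (length(seqs) == 0L)
    return(data.frame(mfe = numeric(), structure = character()))
  if (any(!nzchar(seqs))) stop("empty sequence in fold_hairpin")
  backend <- fold_backend(backend %||% getOption("mirscout.fold_backend", "auto"))
  if (backend == "vienna") {
    out <- system2("RNAfold", args = "--noPS", input = to_rna(seqs),
                   stdout = TRUE, stderr = FALSE)
    out <- out[nzchar(out)]
    if (length(out) != 2L * length(seqs)) stop("unexpected RNAfold output")
    sl <- out[seq(2L, length(out), by = 2L)]
    data.frame(mfe = vapply(sl, parse_vienna_energy, numeric(1),
                            USE.NAMES = FALSE),
               structure = vapply(strsplit(sl, " "), `[`, character(1), 1L,
                                  USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  } else {
    res <- lapply(to_rna(seqs), nussinov_fold_cpp)
    data.frame(mfe = vapply(res, `[[`, numeric(1), "mfe"),
               structure = vapply(res, `[[`, character(1), "structure"),
               stringsAsFactors = FALSE)
  }
}
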