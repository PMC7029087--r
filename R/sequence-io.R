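#' Haplotype alignment
#'
#' Equal-length nucleotide sequences (the mitochondrial Cyt-b fragment in the
#' study system, trimmed to 569 bp). Alphabet is restricted to A, C, G, T, N
#' and the gap character `-`; sequences are upper-cased on construction.
#'
#' @param seqs character vector of equal-length sequences.
#' @param ids sample identifiers (defaults to names of `seqs`).
#' @return an object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seqs, ids = names(seqs)) {
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  if (length(seqs) > 0) {
    len <- nchar(seqs)
    if (length(unique(len)) > 1)
      stop("ragged alignment: sequence lengths ", paste(unique(len), collapse = ", "))
    bad <- grepl("[^ACGTN-]", seqs)
    if (any(bad))
      stop("invalid characters in sequence ", ids[which(bad)[1]])
  }
  structure(list(seqs = unname(seqs), ids = as.character(ids)),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %d sequences of length %d\n",
              length(x$seqs), if (length(x$seqs)) nchar(x$seqs[1]) else 0L))
  invisible(x)
}

#' @export
length.haplotype_alignment <- function(x) length(x$seqs)

#' Alignment length in sites
#' @param x a `haplotype_alignment`.
#' @export
alignment_width <- function(x)
  if (length(x$seqs)) nchar(x$seqs[1]) else 0L

#' Read an aligned FASTA file
#'
#' Order-preserving; headers become sample ids (up to the first whitespace);
#' lowercase bases are upper-cased. An empty file yields an empty alignment.
#'
#' @param path FASTA file.
#' @return a [haplotype_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) return(haplotype_alignment(character(0)))
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  ids <- sub("\\s.*$", "", names(dna))
  haplotype_alignment(seqs, ids)
}

#' Write an aligned FASTA file
#' @param x a [haplotype_alignment()].
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(x$seqs))
    writeLines(c(paste0(">", x$ids[i]), x$seqs[i]), con)
  invisible(path)
}

#' Landmark configurations
#'
#' Two-dimensional landmark data for shell outlines: 4 fixed landmarks
#' (LM1-LM4, points of the aperture/suture) followed by 24 sliding
#' semilandmarks describing the outline curve. The default slider
#' specification lets each semilandmark slide along the chord between its
#' neighbours in outline order (cyclic over the 28 points).
#'
#' @param coords numeric array n x p x 2 (or a single p x 2 matrix).
#' @param ids configuration identifiers.
#' @param fixed indices of fixed landmarks (default 1:4).
#' @param sliders 3-column matrix (before, slider, after); default chains the
#'   remaining points along the outline.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, ids = NULL, fixed = 1:4, sliders = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), 2))
  p <- dim(coords)[2]
  if (dim(coords)[3] != 2) stop("landmark configurations must be 2-D")
  n <- dim(coords)[1]
  if (is.null(ids)) ids <- paste0("cfg_", seq_len(n))
  if (is.null(sliders)) sliders <- default_sliders(p, fixed)
  sliders <- as.matrix(sliders)
  if (ncol(sliders) != 3) stop("sliders must have columns (before, point, after)")
  semis <- setdiff(seq_len(p), fixed)
  if (!setequal(sliders[, 2], semis))
    stop("slider specification must cover exactly the semilandmarks")
  structure(list(coords = coords, ids = as.character(ids),
                 fixed = as.integer(fixed), sliders = sliders),
            class = "landmark_set")
}

default_sliders <- function(p, fixed) {
  semis <- setdiff(seq_len(p), fixed)
  nxt <- function(k) if (k == p) 1L else k + 1L
  prv <- function(k) if (k == 1L) p else k - 1L
  cbind(before = vapply(semis, prv, 1L), point = semis,
        after = vapply(semis, nxt, 1L))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d configurations, %d landmarks (%d fixed + %d sliding)\n",
              dim(x$coords)[1], dim(x$coords)[2], length(x$fixed),
              nrow(x$sliders)))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Parses `LM=` blocks with optional `IMAGE=`, `ID=` and `SCALE=` records.
#' Coordinates are multiplied by the scale factor when present. A block
#' without `ID=` or `IMAGE=` gets the synthetic id `cfg_<k>`.
#'
#' @param path TPS file.
#' @param n_landmarks required landmark count per block (default 28).
#' @return a [landmark_set()].
#' @export
read_tps <- function(path, n_landmarks = 28) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  starts <- grep("^LM\\s*=", ln)
  if (length(starts) == 0) stop("no LM= records in ", path)
  confs <- list(); ids <- character(0)
  for (k in seq_along(starts)) {
    lm <- as.integer(sub("^LM\\s*=\\s*", "", ln[starts[k]]))
    if (lm != n_landmarks)
      stop("block ", k, ": LM=", lm, " but ", n_landmarks, " landmarks required")
    end <- if (k < length(starts)) starts[k + 1] - 1 else length(ln)
    block <- ln[(starts[k] + 1):end]
    xy <- block[seq_len(lm)]
    m <- do.call(rbind, lapply(strsplit(xy, "[[:space:]]+"), as.numeric))
    if (any(is.na(m)) || ncol(m) != 2)
      stop("block ", k, ": malformed coordinate lines")
    rest <- block[-seq_len(lm)]
    gv <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), rest, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", hit[1]) else NA
    }
    sc <- suppressWarnings(as.numeric(gv("SCALE")))
    if (!is.na(sc)) m <- m * sc
    id <- gv("ID"); img <- gv("IMAGE")
    ids <- c(ids, if (!is.na(id) && nzchar(id)) id
             else if (!is.na(img) && nzchar(img)) sub("\\.[^.]*$", "", basename(img))
             else paste0("cfg_", k))
    confs[[k]] <- m
  }
  arr <- array(NA_real_, c(length(confs), n_landmarks, 2))
  for (k in seq_along(confs)) arr[k, , ] <- confs[[k]]
  landmark_set(arr, ids)
}

#' Write a TPS landmark file
#' @param x a [landmark_set()].
#' @param path output file.
#' @export
write_tps <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  p <- dim(x$coords)[2]
  for (k in seq_len(dim(x$coords)[1])) {
    writeLines(paste0("LM=", p), con)
    writeLines(apply(format(x$coords[k, , ], trim = TRUE, digits = 10), 1,
                     paste, collapse = " "), con)
    writeLines(paste0("ID=", x$ids[k]), con)
  }
  invisible(path)
}

GENITAL_FEATURES <- c("filament_length", "total_penis_length",
                      "gland_row_length", "n_rows", "n_glands",
                      "penis_width", "tip_width")

#' Male genital measurements
#'
#' Seven linear/count features per male: filament length, total penis length,
#' gland-row length, number of gland rows, number of glands, penis base width
#' and tip width (lengths in mm). The last two features stand in for the two
#' study features whose identities are not given in the main account; any
#' seven-feature table with these column names is accepted.
#'
#' @param df data frame with `sample_id` and the seven feature columns.
#' @return an object of class `genital_measurements` (a validated data frame).
#' @export
genital_measurements <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(c("sample_id", GENITAL_FEATURES), names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  num <- df[GENITAL_FEATURES]
  ok <- stats::complete.cases(num)
  if (any(num[ok, ] < 0)) stop("genital measurements must be non-negative")
  bad <- ok & df$filament_length > df$total_penis_length
  if (any(bad))
    stop("filament longer than total penis for sample ", df$sample_id[bad][1])
  class(df) <- c("genital_measurements", "data.frame")
  df
}

#' Read genital measurements from CSV
#' @param path CSV with `sample_id` plus the seven feature columns.
#' @export
read_genitalia <- function(path) {
  genital_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}
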