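#' Multilocus microsatellite dataset
#'
#' Container for per-individual diploid genotypes at a set of codominant loci,
#' together with sample metadata (location, geographic context, putative
#' species, ecotype, sex). Genotypes are stored as two allele-label matrices in
#' canonical (lexicographic) order so that unordered-pair equality is exact;
#' missing genotypes have `NA` in both matrices.
#'
#' @param a1,a2 character matrices (samples x loci) of allele labels.
#' @param loci character vector of locus names.
#' @param meta data frame with columns `sample_id`, `location`, `context`
#'   (`"sympatric"`, `"allopatric"` or `"undetermined"`), `species`
#'   (`"fabalis"`, `"obtusata"` or `"unknown"`), `ecotype` (`"ME"`, `"ZS"`,
#'   `"FI"` or `NA`) and `sex` (`"M"`, `"F"` or `"unknown"`).
#' @return an object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(a1, a2, loci, meta) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  n <- nrow(a1)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (ncol(a1) != length(loci))
    stop("number of locus columns does not match `loci`")
  meta <- normalize_meta(meta, n)
  # canonical unordered-pair storage
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  miss <- is.na(a1) != is.na(a2)
  if (any(miss))
    stop("half-missing genotype (one allele NA) for sample ",
         meta$sample_id[which(rowSums(miss) > 0)[1]])
  dimnames(a1) <- dimnames(a2) <- list(meta$sample_id, loci)
  structure(list(a1 = a1, a2 = a2, loci = as.character(loci), meta = meta),
            class = "microsat_dataset")
}

normalize_meta <- function(meta, n) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("metadata rows do not match number of samples")
  defaults <- list(location = "UNK", context = "undetermined",
                   species = "unknown", ecotype = NA_character_,
                   sex = "unknown")
  if (is.null(meta$sample_id)) meta$sample_id <- paste0("ind_", seq_len(n))
  for (f in names(defaults))
    if (is.null(meta[[f]])) meta[[f]] <- rep(defaults[[f]], n)
  meta$sample_id <- as.character(meta$sample_id)
  if (any(!nzchar(meta$location)))
    stop("location codes must be non-empty")
  chk <- function(x, lv) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) stop("invalid metadata value: ", x[bad][1])
    x
  }
  meta$context <- chk(meta$context, c("sympatric", "allopatric", "undetermined"))
  meta$species <- chk(meta$species, c("fabalis", "obtusata", "unknown"))
  meta$ecotype <- chk(meta$ecotype, c("ME", "ZS", "FI"))
  meta$sex     <- chk(meta$sex, c("M", "F", "unknown"))
  # ecotypes are only described for L. fabalis
  meta$ecotype[meta$species == "obtusata"] <- NA_character_
  rownames(meta) <- NULL
  meta[c("sample_id", "location", "context", "species", "ecotype", "sex")]
}

#' @export
print.microsat_dataset <- function(x, ...) {
  nm <- sum(is.na(x$a1))
  cat(sprintf("microsat_dataset: %d samples x %d loci (%d missing genotypes)\n",
              nrow(x$a1), length(x$loci), nm))
  cat("loci:", paste(x$loci, collapse = ", "), "\n")
  tb <- table(x$meta$species)
  cat("species:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.microsat_dataset` <- function(x, i, ...) {
  microsat_dataset(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                   x$loci, x$meta[i, , drop = FALSE])
}

#' Number of samples in a dataset
#' @param x a `microsat_dataset`.
#' @export
n_samples <- function(x) nrow(x$a1)

#' Combine microsatellite datasets by rows
#' @param ... `microsat_dataset` objects sharing the same loci.
#' @param deparse.level unused.
#' @export
rbind.microsat_dataset <- function(..., deparse.level = 1) {
  xs <- list(...)
  loci <- xs[[1]]$loci
  for (x in xs)
    if (!identical(x$loci, loci)) stop("datasets have different loci")
  microsat_dataset(do.call(rbind, lapply(xs, `[[`, "a1")),
                   do.call(rbind, lapply(xs, `[[`, "a2")),
                   loci, do.call(rbind, lapply(xs, `[[`, "meta")))
}

META_COLS <- c("sample_id", "location", "context", "species", "ecotype", "sex")

#' Read multilocus genotypes
#'
#' Reads diploid codominant genotypes from either the documented CSV dialect
#' (metadata columns followed by paired allele columns `<locus>a`, `<locus>b`)
#' or GenePop format with 2- or 3-digit allele codes (`000`/`00` per allele
#' means missing).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @return a [microsat_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, csv = read_genotypes_csv(path),
         genepop = read_genotypes_genepop(path))
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  meta_cols <- intersect(META_COLS, names(df))
  gcols <- setdiff(names(df), META_COLS)
  if (length(gcols) %% 2 != 0)
    stop("odd number of allele columns (", length(gcols),
         "): each locus needs two columns")
  first <- gcols[seq(1, length(gcols), by = 2)]
  loci <- sub("a$", "", first)
  clean <- function(m) { m[m %in% c("", "NA", "000", "00", "0")] <- NA; m }
  a1 <- clean(as.matrix(df[first]))
  a2 <- clean(as.matrix(df[gcols[seq(2, length(gcols), by = 2)]]))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for sample ", df$sample_id[idx[1]],
         " at locus ", loci[idx[2]])
  }
  microsat_dataset(a1, a2, loci, df[meta_cols])
}

read_genotypes_genepop <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  if (length(ln) < 3) stop("not a GenePop file: ", path)
  pop_idx <- grep("^pop$", ln, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no 'Pop' line found in GenePop file")
  hdr <- ln[2:(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(hdr, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  rows <- setdiff(seq_along(ln)[-(1:(pop_idx[1]))], pop_idx)
  pop_of <- findInterval(rows, pop_idx)
  ids <- character(0); A1 <- A2 <- NULL; locs <- character(0)
  a1m <- matrix(NA_character_, length(rows), L)
  a2m <- matrix(NA_character_, length(rows), L)
  for (r in seq_along(rows)) {
    parts <- strsplit(ln[rows[r]], ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop line: ", ln[rows[r]])
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(toks) != L)
      stop("sample ", id, ": expected ", L, " loci, found ", length(toks))
    for (l in seq_len(L)) {
      tk <- toks[l]
      if (!grepl("^[0-9]+$", tk) || !(nchar(tk) %in% c(4, 6)))
        stop("sample ", id, ", locus ", loci[l],
             ": cannot split allele code '", tk, "' into two alleles")
      w <- nchar(tk) / 2
      al <- c(substr(tk, 1, w), substr(tk, w + 1, 2 * w))
      al[al %in% c("00", "000")] <- NA
      a1m[r, l] <- al[1]; a2m[r, l] <- al[2]
    }
    ids <- c(ids, id); locs <- c(locs, paste0("pop", pop_of[r]))
  }
  half <- xor(is.na(a1m), is.na(a2m))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for sample ", ids[idx[1]],
         " at locus ", loci[idx[2]])
  }
  microsat_dataset(a1m, a2m, loci,
                   data.frame(sample_id = ids, location = locs,
                              stringsAsFactors = FALSE))
}

#' Write multilocus genotypes
#'
#' @param x a [microsat_dataset()].
#' @param path output file.
#' @param dialect `"csv"` (round-trips bit-identically through
#'   [read_genotypes()]) or `"genepop"` (3-digit allele codes; allele labels
#'   must be numeric and < 1000).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    out <- x$meta
    for (l in seq_along(x$loci)) {
      out[[paste0(x$loci[l], "a")]] <- ifelse(is.na(x$a1[, l]), "", x$a1[, l])
      out[[paste0(x$loci[l], "b")]] <- ifelse(is.na(x$a2[, l]), "", x$a2[, l])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    pad <- function(m) {
      v <- suppressWarnings(as.integer(m))
      if (any(!is.na(m) & (is.na(v) | v < 0 | v > 999)))
        stop("GenePop output needs numeric allele labels < 1000")
      ifelse(is.na(m), "000", sprintf("%03d", v))
    }
    a1 <- pad(x$a1); a2 <- pad(x$a2)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("hybridscan export", x$loci), con)
    for (loc in unique(x$meta$location)) {
      writeLines("Pop", con)
      for (i in which(x$meta$location == loc))
        writeLines(paste0(x$meta$sample_id[i], " , ",
                          paste0(a1[i, ], a2[i, ], collapse = " ")), con)
    }
  }
  invisible(path)
}
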