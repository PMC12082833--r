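# File formats: FASTA sequences (via Biostrings), a TSV label table with one
# row per sequence (id, w, g; "NA" or an empty field = unknown), plain-matrix
# TSV for the estimated probability matrices, and MEME minimal motif format
# so standard logo/scanning tools can consume the motifs. The TSV matrices
# are the lossless primary record; MEME output is rounded to 6 decimals.

#' Read sequences and labels
#'
#' Reads a FASTA file and its label table and assembles the input tibble for
#' [decompose_motifs()]. Every FASTA record must have exactly one label row;
#' `NA` (case-insensitive) or an empty field encodes an unknown label.
#'
#' @param fasta_path Path to a FASTA file (multi-line records allowed).
#' @param labels_path Path to a TSV with header columns `id`, `w`, `g`.
#' @param alphabet Passed to [motif_alphabet()]; residues are validated.
#' @return A tibble with columns `id`, `seq`, `w`, `g` in FASTA order.
#' @export
read_motif_data <- function(fasta_path, labels_path, alphabet = "AA") {
  letters_out <- motif_alphabet(alphabet)
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  lab <- readr::read_tsv(labels_path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (!all(c("id", "w", "g") %in% names(lab))) {
    stop("label table must have header columns `id`, `w`, `g`")
  }
  if (anyDuplicated(lab$id)) {
    stop(sprintf("duplicate id '%s' in label table (line %d)",
                 lab$id[duplicated(lab$id)][1], which(duplicated(lab$id))[1] + 1L))
  }
  missing_ids <- setdiff(ids, lab$id)
  if (length(missing_ids)) stop("no label row for sequence id: ", missing_ids[1])
  extra_ids <- setdiff(lab$id, ids)
  if (length(extra_ids)) stop("label row without FASTA record: ", extra_ids[1])

  parse_label <- function(x, name) {
    out <- integer(length(x))
    for (k in seq_along(x)) {
      v <- trimws(x[k])
      if (v == "" || toupper(v) == "NA") out[k] <- NA_integer_
      else if (v %in% c("0", "1")) out[k] <- as.integer(v)
      else stop(sprintf("illegal %s label '%s' (label table line %d)", name, v, k + 1L))
    }
    out
  }
  lab <- lab[match(ids, lab$id), ]
  seq_chr <- as.character(seqs)
  for (k in seq_along(seq_chr)) {
    encode_seq(seq_chr[k], letters_out, what = sprintf("FASTA record '%s'", ids[k]))
  }
  tibble::tibble(id = ids, seq = unname(seq_chr),
                 w = parse_label(lab$w, "w"), g = parse_label(lab$g, "g"))
}

#' Write sequences and labels
#'
#' Inverse of [read_motif_data()]: writes the FASTA file and the TSV label
#' table (unknown labels written as `NA`). Round-trips losslessly.
#'
#' @param data Tibble with columns `id`, `seq`, `w`, `g`.
#' @param fasta_path,labels_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_motif_data <- function(data, fasta_path, labels_path) {
  x <- Biostrings::BStringSet(stats::setNames(data$seq, data$id))
  Biostrings::writeXStringSet(x, fasta_path)
  lab <- data.frame(id = data$id,
                    w = ifelse(is.na(data$w), "NA", as.character(data$w)),
                    g = ifelse(is.na(data$g), "NA", as.character(data$g)))
  readr::write_tsv(lab, labels_path, progress = FALSE)
  invisible(c(fasta_path, labels_path))
}

#' Export estimated motifs
#'
#' Writes the MAP background vector and the two motif matrices as plain TSV
#' matrices (letters as rows, positions as columns) and as a MEME minimal
#' motif file with the MAP background as the background frequencies. Columns
#' are renormalized to sum to one before writing.
#'
#' @param fit An `hm_fit` object (the MAP estimate is exported).
#' @param prefix Output path prefix; files `<prefix>_background.tsv`,
#'   `<prefix>_motif1.tsv`, `<prefix>_motif2.tsv` and `<prefix>.meme` are
#'   written.
#' @return Character vector of the written paths, invisibly.
#' @export
write_motifs <- function(fit, prefix) {
  stopifnot(inherits(fit, "hm_fit"))
  p <- fit$problem
  map <- map_estimate(fit)
  norm_cols <- function(m) sweep(m, 2, colSums(m), "/")
  th0 <- map$theta0 / sum(map$theta0)
  M1 <- norm_cols(map$Theta1)
  M2 <- norm_cols(map$Theta2)
  paths <- c(background = paste0(prefix, "_background.tsv"),
             motif1 = paste0(prefix, "_motif1.tsv"),
             motif2 = paste0(prefix, "_motif2.tsv"),
             meme = paste0(prefix, ".meme"))
  write_matrix_tsv(matrix(th0, ncol = 1, dimnames = list(p$letters, "bg")),
                   paths["background"])
  write_matrix_tsv(`dimnames<-`(M1, list(p$letters, paste0("p", seq_len(p$J)))),
                   paths["motif1"])
  write_matrix_tsv(`dimnames<-`(M2, list(p$letters, paste0("p", seq_len(p$J2)))),
                   paths["motif2"])

  con <- file(paths["meme"], "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(p$letters, collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", p$letters, th0), collapse = " "), ""), con)
  write_one <- function(name, M, nsites) {
    writeLines(c(paste("MOTIF", name),
                 sprintf("letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
                         nrow(M), ncol(M), nsites)), con)
    for (j in seq_len(ncol(M))) {
      writeLines(paste(sprintf("%.6f", M[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  write_one("motif1", M1, sum(map$w == 1))
  write_one("motif2", M2, sum(map$g == 1))
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(letter = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Read a probability matrix written by [write_motifs()]
#'
#' @param path Path to a TSV with a `letter` column and one column per
#'   position.
#' @return A numeric matrix with letter rownames.
#' @export
read_motif_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    letter = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$letter
  m
}

#' Read a MEME minimal motif file
#'
#' Parses the subset of the MEME minimal format written by [write_motifs()]:
#' the alphabet line, background frequencies, and letter-probability
#' matrices.
#'
#' @param path Path to a `.meme` file.
#' @return A list with `alphabet` (character vector), `background` (named
#'   numeric vector) and `motifs` (named list of K x w matrices, letters as
#'   rows).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  al_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (!length(al_line)) stop("not a MEME minimal motif file: no ALPHABET line")
  letters_out <- strsplit(trimws(sub("^ALPHABET=", "", al_line[1])), "")[[1]]
  K <- length(letters_out)
  bg <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(toks[seq(2, length(toks), 2)]),
                          toks[seq(1, length(toks), 2)])
  }
  motifs <- list()
  at <- grep("^MOTIF ", lines)
  for (s in at) {
    name <- strsplit(trimws(sub("^MOTIF ", "", lines[s])), "\\s+")[[1]][1]
    hdr <- lines[s + 1]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
    rows <- lines[(s + 2):(s + 1 + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(K)))
    motifs[[name]] <- `dimnames<-`(t(m), list(letters_out, paste0("p", seq_len(w))))
  }
  list(alphabet = letters_out, background = bg, motifs = motifs)
}
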