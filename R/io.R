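# Readers and writers. Canonical tabular dialect: TSV, header row, UTF-8,
# '.' decimal separator, no quoting.

#' Write a data frame as canonical TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a canonical TSV
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, encoding = "UTF-8")
}

#' Read coding sequences from FASTA
#'
#' Headers follow `>transcript_id gene=gene_id`; a missing `gene=` tag
#' falls back to the transcript id. Sequences are uppercased and validated:
#' ACGT alphabet, length divisible by 3, ATG start, in-frame stop only at
#' the terminus. Duplicate transcript ids are rejected.
#'
#' @param path FASTA file.
#' @return Data frame with `transcript_id`, `gene_id`, `cds`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- ifelse(grepl("gene=", headers),
                  sub("^.*gene=([^ ]+).*$", "\\1", headers), ids)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    validate_cds(seqs[i], ids[i])
  }
  data.frame(transcript_id = ids, gene_id = genes, cds = unname(seqs),
             stringsAsFactors = FALSE)
}

validate_cds <- function(cds, id) {
  if (!grepl("^[ACGT]+$", cds)) {
    stop("transcript ", id, ": non-ACGT characters in sequence")
  }
  if (nchar(cds) %% 3 != 0) {
    stop("transcript ", id, ": CDS length not divisible by 3")
  }
  if (substr(cds, 1, 3) != "ATG") {
    stop("transcript ", id, ": CDS does not start with ATG")
  }
  aa <- translate_codon_table(cds)
  body <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("\\*", body)) {
    stop("transcript ", id, ": internal in-frame stop codon")
  }
  invisible(TRUE)
}

#' Write coding sequences as FASTA
#'
#' @param transcripts Data frame with `transcript_id`, `gene_id`, `cds`.
#' @param path Output path.
#' @export
write_cds_fasta <- function(transcripts, path) {
  lines <- unlist(lapply(seq_len(nrow(transcripts)), function(i) {
    c(sprintf(">%s gene=%s", transcripts$transcript_id[i],
              transcripts$gene_id[i]),
      transcripts$cds[i])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a somatic variant table
#'
#' Two dialects carry the same content: `"tsv"` with columns
#' `transcript_id`, `cds_position`, `ref_base`, `alt_base` (optionally
#' `sample_id`), and `"vcf_minimal"`, a minimal VCF whose CHROM column holds
#' the transcript id, POS the 1-based CDS position, and ID the sample id.
#' When `transcripts` is supplied, each ref base is validated against the
#' CDS and positions are range-checked.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf_minimal"`.
#' @param transcripts Optional transcript table for validation.
#' @return Data frame `transcript_id`, `cds_position`, `ref_base`,
#'   `alt_base`, `sample_id`.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf_minimal"),
                          transcripts = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    v <- read_tsv_file(path)
    need <- c("transcript_id", "cds_position", "ref_base", "alt_base")
    if (!all(need %in% names(v))) {
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (!"sample_id" %in% names(v)) v$sample_id <- NA_character_
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    if (length(lines) == 0 || !startsWith(lines[1], "#CHROM")) {
      stop("minimal VCF must have a #CHROM header line")
    }
    body <- lines[-1]
    v <- if (length(body) == 0) {
      data.frame(transcript_id = character(0), cds_position = integer(0),
                 ref_base = character(0), alt_base = character(0),
                 sample_id = character(0))
    } else {
      f <- strsplit(body, "\t", fixed = TRUE)
      data.frame(
        transcript_id = vapply(f, `[`, "", 1),
        cds_position = as.integer(vapply(f, `[`, "", 2)),
        ref_base = vapply(f, `[`, "", 4),
        alt_base = vapply(f, `[`, "", 5),
        sample_id = vapply(f, `[`, "", 3),
        stringsAsFactors = FALSE
      )
    }
    v$sample_id[v$sample_id == "."] <- NA_character_
  }
  v$cds_position <- as.integer(v$cds_position)
  if (!is.null(transcripts)) {
    m <- match(v$transcript_id, transcripts$transcript_id)
    if (anyNA(m)) {
      stop("unknown transcript(s): ",
           paste(unique(v$transcript_id[is.na(m)]), collapse = ", "))
    }
    for (i in seq_len(nrow(v))) {
      cds <- transcripts$cds[m[i]]
      if (v$cds_position[i] < 1 || v$cds_position[i] > nchar(cds)) {
        stop("variant ", v$transcript_id[i], ":", v$cds_position[i],
             " out of CDS range (1..", nchar(cds), ")")
      }
      have <- substr(cds, v$cds_position[i], v$cds_position[i])
      if (have != toupper(v$ref_base[i])) {
        stop("ref mismatch for ", v$transcript_id[i], ":",
             v$cds_position[i], " (file says ", v$ref_base[i],
             ", CDS has ", have, ")")
      }
    }
  }
  v[, c("transcript_id", "cds_position", "ref_base", "alt_base", "sample_id")]
}

#' Write a variant table as minimal VCF
#'
#' @param variants Data frame from [read_variants()] or the simulator.
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=gliomaTIL minimal CDS-coordinate dialect",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  id <- ifelse(is.na(variants$sample_id), ".", variants$sample_id)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$transcript_id, variants$cds_position, id,
                  variants$ref_base, variants$alt_base)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a TCR clone table (immunoSEQ-like TSV)
#'
#' @param path TSV with columns `cdr3_nt`, `cdr3_aa`, `reads`,
#'   `productive` (logical or `true`/`false`).
#' @param sample_id,group Sample annotation.
#' @return A [repertoire()] clone table.
#' @export
read_repertoire_tsv <- function(path, sample_id = NA_character_,
                                group = NA_character_) {
  x <- read_tsv_file(path)
  need <- c("cdr3_nt", "cdr3_aa", "reads", "productive")
  if (!all(need %in% names(x))) {
    stop("repertoire TSV must have columns: ", paste(need, collapse = ", "))
  }
  x$productive <- as.logical(x$productive) |
    tolower(as.character(x$productive)) %in% "true"
  repertoire(x, sample_id = sample_id, group = group)
}

#' Read a long-format Ct table
#'
#' @param path TSV with columns `sample_id`, `group`, `gene`, `ct`.
#' @return Data frame.
#' @export
read_ct_tsv <- function(path) {
  x <- read_tsv_file(path)
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(x))) {
    stop("Ct TSV must have columns: ", paste(need, collapse = ", "))
  }
  x$ct <- as.numeric(x$ct)
  if (any(x$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  x
}

#' Read a long-format expression table
#'
#' @param path TSV with columns `gene_id`, `sample_id`, `fpkm`.
#' @return Data frame.
#' @export
read_expression_tsv <- function(path) {
  x <- read_tsv_file(path)
  need <- c("gene_id", "sample_id", "fpkm")
  if (!all(need %in% names(x))) {
    stop("expression TSV must have columns: ", paste(need, collapse = ", "))
  }
  x$fpkm <- as.numeric(x$fpkm)
  x
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path Text file.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read cell centroids from CSV
#'
#' @param path CSV with header `x_px,y_px,marker`.
#' @return Data frame.
#' @export
read_centroids_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_px", "y_px", "marker")
  if (!all(need %in% names(x))) {
    stop("centroid CSV must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Write cell centroids as CSV
#'
#' @param cells Data frame with `x_px`, `y_px`, `marker`.
#' @param path Output path.
#' @export
write_centroids_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grayscale image or mask (TIFF or PNG)
#'
#' 8/16-bit grayscale; any nonzero pixel is foreground when the image is
#' used as a mask. Returned in x-by-y orientation (column = image row).
#'
#' @param path `.tif`, `.tiff` or `.png` file.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  t(img) # row-major image to x-by-y matrix
}

#' Write a binary mask as PNG
#'
#' @param mask Integer/logical matrix in x-by-y orientation.
#' @param path Output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(t(mask > 0) * 1.0, path)
  invisible(path)
}
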