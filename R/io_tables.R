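#' Read a variant table into a call set
#'
#' Reads one genome's variant calls relative to the shared reference from one
#' of three dialects:
#'
#' * `"gd"` — a GenomeDiff-style flat file (read-only subset: `SNP`, `INS`,
#'   `DEL`, `MOB` entry types; all other entry types are ignored with a
#'   logged count). Trailing `key=value` fields `frequency=`, `gene=` and
#'   `syn=` are honoured.
#' * `"vcf"` — a VCF sites file read via \pkg{vcfR}. Allele frequencies are
#'   taken from the `AF` INFO field and are mandatory for population-role
#'   samples. Files written by [write_variant_table()] carry `KIND`/`ALTD`
#'   INFO fields that restore the exact site descriptors; plain caller VCFs
#'   fall back to REF/ALT length inference (1 bp vs 1 bp = SNP, otherwise a
#'   small indel).
#' * `"tsv"` — the package's native tab-separated table with a
#'   `chrom pos kind alt gene syn freq` header.
#'
#' Coordinates are 1-based inclusive throughout (identical to the VCF
#' convention). Records on contigs not listed in `known_chroms` are dropped
#' with a logged count.
#'
#' @param path input file.
#' @param dialect `"gd"`, `"vcf"`, `"tsv"`, or `"auto"` (sniffed from the
#'   file extension).
#' @param sample_id sample name; defaults to the file base name.
#' @param role experimental role of the genome (see [call_set()]).
#' @param known_chroms optional character vector of recognized contigs;
#'   `NULL` keeps everything.
#' @param large_deletion_min GD `DEL` entries at least this long (bp) become
#'   `large_deletion` sites; shorter ones become `small_indel`.
#' @return a [call_set()].
#' @export
read_variant_table <- function(path, dialect = c("auto", "gd", "vcf", "tsv"),
                               sample_id = NULL, role = "recombinant",
                               known_chroms = NULL, large_deletion_min = 50L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, gd = "gd", vcf = "vcf", tsv = "tsv",
                      stop("cannot sniff dialect from extension '.", ext, "'"))
  }
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  v <- switch(dialect,
              gd = read_gd(path, large_deletion_min),
              vcf = read_vcf_sites(path),
              tsv = read_tsv_sites(path))
  if (!is.null(known_chroms)) {
    drop <- !(v$chrom %in% known_chroms)
    if (any(drop)) {
      message(sum(drop), " record(s) on unknown contigs dropped from ", path)
      v <- v[!drop, , drop = FALSE]
    }
  }
  if (role == "population" && nrow(v) > 0L && anyNA(v$freq))
    stop("population sample '", sample_id, "': records without a frequency")
  call_set(sample_id, role, order_sites(v))
}

read_gd <- function(path, large_deletion_min) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  n_ignored <- 0L
  for (j in seq_along(idx)) {
    i <- idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    type <- f[1]
    if (!type %in% c("SNP", "INS", "DEL", "MOB")) {
      n_ignored <- n_ignored + 1L
      next
    }
    if (length(f) < 6L)
      stop("malformed GenomeDiff line ", i, " in ", path)
    chrom <- f[4]
    pos <- suppressWarnings(as.integer(f[5]))
    if (is.na(pos)) stop("malformed GenomeDiff line ", i, " in ", path,
                         ": bad position '", f[5], "'")
    extra <- parse_kv(f[-(1:6)])
    row <- switch(type,
      SNP = list(kind = "SNP", alt = f[6]),
      INS = list(kind = "small_indel", alt = paste0("+", f[6])),
      DEL = {
        size <- suppressWarnings(as.numeric(f[6]))
        if (is.na(size) || size < 1)
          stop("malformed GenomeDiff line ", i, " in ", path, ": bad DEL size")
        if (size >= large_deletion_min)
          list(kind = "large_deletion", alt = format_span(size))
        else list(kind = "small_indel", alt = paste0("-", format_span(size)))
      },
      MOB = list(kind = "IS_insertion", alt = f[6]))
    rows[[j]] <- data.frame(
      chrom = chrom, pos = pos, kind = row$kind, alt = row$alt,
      gene = extra[["gene"]] %||% NA_character_,
      syn = extra[["syn"]] %||% NA_character_,
      freq = as.numeric(extra[["frequency"]] %||% NA),
      stringsAsFactors = FALSE)
  }
  if (n_ignored > 0L)
    message(n_ignored, " unsupported GenomeDiff entr(ies) ignored in ", path)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(variant_table())
  out <- do.call(rbind, rows)
  validate_variant_table(out)
  out
}

parse_kv <- function(fields) {
  kv <- fields[grepl("=", fields, fixed = TRUE)]
  if (length(kv) == 0L) return(list())
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) paste(p[-1], collapse = "=")),
                  vapply(parts, `[[`, character(1), 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_span <- function(x) format(x, scientific = FALSE, trim = TRUE)

read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) return(variant_table())
  info_kind <- vcfR::extract.info(v, "KIND")
  info_altd <- vcfR::extract.info(v, "ALTD")
  info_af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  info_gene <- vcfR::extract.info(v, "GENE")
  info_syn <- vcfR::extract.info(v, "SYN")
  n <- nrow(fx)
  kind <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(info_kind) && !is.na(info_kind[i])) {
      kind[i] <- info_kind[i]
      alt[i] <- if (!is.null(info_altd) && !is.na(info_altd[i]))
        utils::URLdecode(info_altd[i]) else fx[i, "ALT"]
    } else if (nchar(fx[i, "REF"]) == 1L && nchar(fx[i, "ALT"]) == 1L) {
      kind[i] <- "SNP"; alt[i] <- fx[i, "ALT"]
    } else {
      kind[i] <- "small_indel"; alt[i] <- fx[i, "ALT"]
    }
  }
  out <- data.frame(
    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]), kind = kind,
    alt = alt,
    gene = if (is.null(info_gene)) NA_character_ else as.character(info_gene),
    syn = if (is.null(info_syn)) NA_character_ else as.character(info_syn),
    freq = if (is.null(info_af)) NA_real_ else info_af,
    stringsAsFactors = FALSE)
  validate_variant_table(out)
  out
}

read_tsv_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(chrom = "character", alt = "character",
                                         gene = "character", syn = "character"))
  required <- c("chrom", "pos", "kind", "alt")
  if (!all(required %in% names(df)))
    stop("malformed TSV ", path, ": needs columns ",
         paste(required, collapse = ", "))
  for (col in c("gene", "syn")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$freq)) df$freq <- NA_real_
  bad <- which(is.na(df$pos))
  if (length(bad) > 0L)
    stop("malformed TSV line ", bad[1] + 1L, " in ", path, ": bad position")
  df <- df[, c("chrom", "pos", "kind", "alt", "gene", "syn", "freq")]
  df$pos <- as.integer(df$pos)
  validate_variant_table(df)
  df
}

#' Write a call set to disk
#'
#' Inverse of [read_variant_table()] for every supported dialect. Output row
#' order is a pure function of site identity (`chrom, pos, kind, alt`), so
#' two writes of the same call set are byte-identical.
#'
#' @param x a [call_set()].
#' @param path output file.
#' @param dialect `"tsv"`, `"gd"`, or `"vcf"` (default sniffed from the
#'   extension).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, dialect = c("auto", "gd", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- switch(tolower(tools::file_ext(path)), gd = "gd", vcf = "vcf",
                      tsv = "tsv", stop("cannot sniff dialect for ", path))
  v <- order_sites(as_variants(x))
  switch(dialect,
         tsv = write_tsv_sites(v, path),
         gd = write_gd(v, path, if (inherits(x, "call_set")) x$role else "recombinant"),
         vcf = write_vcf_sites(v, path))
  invisible(path)
}

write_tsv_sites <- function(v, path) {
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

write_gd <- function(v, path, role) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#=GENOME_DIFF\t1.0", con)
  if (nrow(v) == 0L) return(invisible(path))
  for (i in seq_len(nrow(v))) {
    extras <- character()
    if (!is.na(v$freq[i])) extras <- c(extras, paste0("frequency=", v$freq[i]))
    if (!is.na(v$gene[i])) extras <- c(extras, paste0("gene=", v$gene[i]))
    if (!is.na(v$syn[i])) extras <- c(extras, paste0("syn=", v$syn[i]))
    fields <- switch(v$kind[i],
      SNP = c("SNP", i, ".", v$chrom[i], v$pos[i], v$alt[i]),
      small_indel = {
        if (startsWith(v$alt[i], "+"))
          c("INS", i, ".", v$chrom[i], v$pos[i], sub("^\\+", "", v$alt[i]))
        else c("DEL", i, ".", v$chrom[i], v$pos[i], sub("^-", "", v$alt[i]))
      },
      large_deletion = c("DEL", i, ".", v$chrom[i], v$pos[i], v$alt[i]),
      IS_insertion = c("MOB", i, ".", v$chrom[i], v$pos[i], v$alt[i]))
    writeLines(paste(c(fields, extras), collapse = "\t"), con)
  }
  invisible(path)
}

write_vcf_sites <- function(v, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Site kind\">",
    "##INFO=<ID=ALTD,Number=1,Type=String,Description=\"Allele descriptor (URL-encoded)\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene name\">",
    "##INFO=<ID=SYN,Number=1,Type=String,Description=\"Coding annotation\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v) == 0L) return(invisible(path))
  is_snp <- v$kind == "SNP"
  alt_col <- ifelse(is_snp, v$alt, paste0("<", toupper(v$kind), ">"))
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- c(paste0("KIND=", v$kind[i]),
               paste0("ALTD=", utils::URLencode(v$alt[i], reserved = TRUE)))
    if (!is.na(v$freq[i])) parts <- c(parts, paste0("AF=", v$freq[i]))
    if (!is.na(v$gene[i])) parts <- c(parts, paste0("GENE=", v$gene[i]))
    if (!is.na(v$syn[i])) parts <- c(parts, paste0("SYN=", v$syn[i]))
    paste(parts, collapse = ";")
  }, character(1))
  writeLines(paste(v$chrom, v$pos, ".", "N", alt_col, ".", "PASS", info,
                   sep = "\t"), con)
  invisible(path)
}

#' Write a labeled-variant table
#'
#' One row per labeled site with columns `chrom, pos, kind, alt, label,
#' in_deleted_region, donor_origin, gene, syn, recombinant_id`, sorted by
#' site identity so repeated runs on the same input are byte-identical. An
#' empty input produces a header-only file.
#'
#' @param labeled a labeled-variant data.frame from [label_mutations()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @seealso [read_labeled_table()]
#' @export
write_labeled_table <- function(labeled, path) {
  cols <- c("chrom", "pos", "kind", "alt", "label", "in_deleted_region",
            "donor_origin", "gene", "syn", "recombinant_id")
  if (nrow(labeled) > 0L) {
    labeled <- order_sites(labeled)
  }
  for (col in cols) if (is.null(labeled[[col]])) {
    empty <- if (col == "in_deleted_region") logical(0) else character(0)
    labeled[[col]] <- if (nrow(labeled) == 0L) empty else NA
  }
  utils::write.table(labeled[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a labeled-variant table written by [write_labeled_table()]
#'
#' @param path input TSV.
#' @return a labeled-variant data.frame.
#' @export
read_labeled_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(chrom = "character", alt = "character",
                                         label = "character"))
  df$pos <- as.integer(df$pos)
  df$in_deleted_region <- as.logical(df$in_deleted_region)
  for (col in c("donor_origin", "gene", "syn", "recombinant_id"))
    df[[col]] <- as.character(df[[col]])
  df
}

#' Read a coverage summary table
#'
#' Expects a TSV with columns `sample_id, chrom_cov, plasmid_cov`, the mean
#' number of mapped reads per site on the chromosome and on the plasmid.
#'
#' @param path input TSV.
#' @return data.frame of coverage pairs.
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "chrom_cov", "plasmid_cov")
  if (!all(required %in% names(df)))
    stop("coverage table needs columns ", paste(required, collapse = ", "))
  if (any(df$chrom_cov < 0 | df$plasmid_cov < 0))
    stop("coverage values must be nonnegative")
  df
}
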