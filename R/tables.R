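# Tabular data models: TSS maps, differential-expression tables, SNP
# records. All are plain data.frames with fixed column contracts, read and
# written as headered TSV (plus a VCF-lite reader for SNPs).

#' Construct a TSS map
#'
#' @param gene_id Character gene identifiers (must be unique).
#' @param contig Contig of each TSS.
#' @param tss 1-based TSS position.
#' @param strand Optional strand (`+`/`-`); informational only — distance
#'   computations are strand-agnostic.
#' @return A data frame with columns `gene_id`, `contig`, `tss`, `strand`.
#' @export
tss_map <- function(gene_id, contig, tss, strand = "*") {
  if (anyDuplicated(gene_id))
    .stopf("duplicate gene_id in TSS map: %s",
           paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  data.frame(gene_id = as.character(gene_id), contig = as.character(contig),
             tss = as.integer(tss),
             strand = rep_len(as.character(strand), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Read / write a TSS map as headered TSV
#' @param path File path.
#' @return `read_tss`: the TSS map data frame.
#' @export
read_tss <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .need_cols(df, c("gene_id", "contig", "tss"), "TSS table")
  if (!"strand" %in% names(df)) df$strand <- "*"
  tss_map(df$gene_id, df$contig, df$tss, df$strand)
}

#' @rdname read_tss
#' @param tss A TSS map data frame.
#' @export
write_tss <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a differential-expression table
#'
#' Carries both the log2 fold change and the signed linear fold change the
#' field prints in figures (negative = down-regulated in the knockdown; a
#' 18.4-fold reduction is `fc = -18.4`, `log2fc = -log2(18.4)`). When `fc` is
#' omitted it is derived as `sign(log2fc) * 2^|log2fc|`.
#'
#' @param gene_id Character gene ids (unique).
#' @param log2fc Log2 fold change.
#' @param padj Adjusted p-value in `[0, 1]` (NA allowed, e.g. for genes
#'   removed by independent filtering).
#' @param fc Optional signed linear fold change.
#' @return A data frame with columns `gene_id`, `log2fc`, `fc`, `padj`.
#' @export
de_table <- function(gene_id, log2fc, padj, fc = NULL) {
  if (anyDuplicated(gene_id)) .stopf("duplicate gene_id in DE table")
  if (any(!is.na(padj) & (padj < 0 | padj > 1)))
    .stopf("padj outside [0, 1]")
  if (is.null(fc)) fc <- ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
  data.frame(gene_id = as.character(gene_id), log2fc = as.numeric(log2fc),
             fc = as.numeric(fc), padj = as.numeric(padj),
             stringsAsFactors = FALSE)
}

#' Read / write a differential-expression table as headered TSV
#' @param path File path.
#' @return `read_de_table`: the DE table data frame.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .need_cols(df, c("gene_id", "log2fc", "padj"), "DE table")
  de_table(df$gene_id, df$log2fc, df$padj,
           fc = if ("fc" %in% names(df)) df$fc else NULL)
}

#' @rdname read_de_table
#' @param de A DE table data frame.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct biallelic SNP records
#'
#' @param id Variant identifiers (e.g. rs numbers).
#' @param contig Contig.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Single reference/alternate bases in `{A, C, G, T}`,
#'   `ref != alt`.
#' @return A data frame with columns `id`, `contig`, `pos`, `ref`, `alt`.
#' @export
snp_record <- function(id, contig, pos, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T")))
    .stopf("ref/alt alleles must be single bases in {A, C, G, T}")
  if (any(ref == alt)) .stopf("ref allele equals alt allele")
  data.frame(id = as.character(id), contig = as.character(contig),
             pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Read / write SNP records in VCF-lite format
#'
#' VCF-lite is the five-column head of a VCF body: CHROM, POS (1-based), ID,
#' REF, ALT, tab-separated, `#`-prefixed headers ignored.
#'
#' @param path File path.
#' @return `read_snps`: a SNP record data frame.
#' @export
read_snps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(snp_record(character(0), character(0), integer(0),
                      character(0), character(0)))
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 5L))
    .stopf("malformed VCF-lite line %d: fewer than 5 fields",
           which(lengths(fields) < 5L)[1L])
  get <- function(k) vapply(fields, `[[`, character(1), k)
  snp_record(id = get(3L), contig = get(1L), pos = as.integer(get(2L)),
             ref = get(4L), alt = get(5L))
}

#' @rdname read_snps
#' @param snps A SNP record data frame.
#' @export
write_snps <- function(snps, path) {
  lines <- c("#CHROM\tPOS\tID\tREF\tALT",
             sprintf("%s\t%d\t%s\t%s\t%s", snps$contig, snps$pos, snps$id,
                     snps$ref, snps$alt))
  writeLines(lines, path)
  invisible(path)
}
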