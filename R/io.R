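# Export helpers: GFF3 and per-class FASTA for repertoires, TSV summaries.

#' Write an OR repertoire as GFF3, per-class FASTA, and a TSV summary
#'
#' Internal 0-based half-open coordinates are converted to 1-based inclusive
#' GFF3 coordinates; records carry `class=` and `family=` attributes.
#'
#' @param repertoire [annotate_genome()] output.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_repertoire <- function(repertoire, out_dir) {
  stopifnot(inherits(repertoire, "fishor_repertoire"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- repertoire$records
  gff <- file.path(out_dir, "or_loci.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  if (nrow(rec)) {
    writeLines(sprintf(
      "%s\tfishor\tgene\t%d\t%d\t%s\t%s\t.\tID=%s;class=%s;family=%s",
      rec$scaffold, rec$start + 1L, rec$end, format(rec$score),
      rec$strand, rec$locus_id, rec$class, rec$family), con)
  }
  close(con)
  paths <- gff
  for (cls in unique(rec$class)) {
    f <- file.path(out_dir, paste0(cls, ".fasta"))
    con <- file(f, "w")
    sub <- rec[rec$class == cls, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      writeLines(paste0(">", sub$locus_id[i], " class=", cls,
                        " family=", sub$family[i]), con)
      s <- sub$seq[i]
      writeLines(substring(s, seq(1, nchar(s), 80),
                           pmin(nchar(s), seq(80, nchar(s) + 79, 80))), con)
    }
    close(con)
    paths <- c(paths, f)
  }
  summ <- file.path(out_dir, "summary.tsv")
  cc <- repertoire$class_counts
  fc <- repertoire$family_counts
  row <- data.frame(species = repertoire$species, t(as.matrix(cc)),
                    stringsAsFactors = FALSE)
  for (f in names(fc)) row[[paste0("family_", f)]] <- as.integer(fc[[f]])
  write.table(row, summ, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, summ))
}

#' Write a per-branch events table and sweep results as TSV
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
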