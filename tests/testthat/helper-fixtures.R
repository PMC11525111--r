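# Small file fixtures built in code at test time.

write_weights_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                  header = c("rsID", "chr_name", "chr_position",
                                             "effect_allele", "other_allele",
                                             "effect_weight"),
                                  comments = character(0)) {
  writeLines(c(comments, paste(header, collapse = "\t"), rows), path)
  path
}

# rows: list of c(id, chr, pos, ref, alt, cells...) character vectors
write_vcf_fixture <- function(rows, sample_ids, format = "GT",
                              path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"),
    vapply(rows, function(r) {
      paste(c(r[2], r[3], r[1], r[4], r[5], ".", "PASS", ".", format,
              r[-(1:5)]), collapse = "\t")
    }, character(1))
  ), path)
  path
}

simple_weights <- function(ids, effect, other, w,
                           chr = rep("1", length(ids)),
                           pos = seq(100, by = 100, length.out = length(ids))) {
  out <- data.frame(variant_id = ids, chromosome = chr, position = pos,
                    effect_allele = effect, other_allele = other,
                    effect_weight = w, stringsAsFactors = FALSE)
  class(out) <- c("grs_weights", "data.frame")
  out
}

# expand a 2x2 table (a = exposed cases, b = exposed controls,
# c = unexposed cases, d = unexposed controls) into rows
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d))
  )
}

# exhaustive pairwise AUC oracle
auc_pair_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (u in cases) for (v in controls) {
    tot <- tot + (u > v) + 0.5 * (u == v)
  }
  tot / (length(cases) * length(controls))
}
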