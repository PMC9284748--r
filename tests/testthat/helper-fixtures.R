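# Gene-group table built from the published per-species family counts:
# sorbitol-transporter-like (SOT) foreground counts 24/15/8/8 and
# sorbitol-dehydrogenase-like (SDH) foreground counts 13/15/1/1.
paper_style_table <- function() {
  sot_n <- c(pear = 24, apple = 15, peach = 8, mei = 8)
  sdh_n <- c(pear = 13, apple = 15, peach = 1, mei = 1)
  mk <- function(fam, n_by_sp) {
    do.call(rbind, lapply(names(n_by_sp), function(sp) {
      data.frame(gene_id = sprintf("%s_%s_%02d", fam, sp,
                                   seq_len(n_by_sp[[sp]])),
                 species = sp, family = fam, group = "SPG",
                 stringsAsFactors = FALSE)
    }))
  }
  bg <- data.frame(gene_id = c("SOT_ara_01", "SDH_ara_01"),
                   species = "arabidopsis", family = c("SOT", "SDH"),
                   group = "SAG", stringsAsFactors = FALSE)
  rbind(mk("SOT", sot_n), mk("SDH", sdh_n), bg)
}
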