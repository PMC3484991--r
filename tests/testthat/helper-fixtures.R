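# shared fixtures: small generator configs and a hand-built cascade input

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400, n_leydig_markers = 6, n_sertoli_markers = 8,
         n_gonocyte_markers = 20, seed = 42),
    list(...))
  do.call(generator_config, args)
}

# a bare DE table with the attributes run_cascade() needs
make_de <- function(genes, fold, q, platform, contrast = NULL) {
  structure(data.frame(gene = genes, fold = fold, q = q,
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"),
            platform = platform, contrast = contrast)
}

# ten-gene hand fixture exercising every cascade rule and boundary.
# column legend, one gene per scenario:
#   PASS     clean candidate through all seven steps
#   SIG110   Mafb+ signal exactly at the floor (strict >) -> culled step 1
#   LOWQ     q above the FDR cutoff at step 1 -> culled
#   GONO     Pou5f1+ signal above the ceiling -> discarded step 2
#   GONO200  Pou5f1+ signal exactly 200 (strict >) -> survives step 2
#   SERT     Sox9+/Mafb+ ratio above 1 -> culled step 3
#   RATIO1   ratio exactly 1.0 -> survives step 3
#   NOWT     whole-testis induction absent -> culled step 4
#   MOUSEHIT suppressed in mouse DBP -> culled step 6
#   CARRY    absent from every 3' platform -> carried through steps 4-6
cascade_fixture <- function() {
  genes <- c("PASS", "SIG110", "LOWQ", "GONO", "GONO200", "SERT", "RATIO1",
             "NOWT", "MOUSEHIT", "CARRY")
  n <- length(genes)
  sig_mafb <- c(500, 110, 500, 500, 500, 200, 300, 500, 500, 500)
  sig_pou <- c(50, 50, 50, 250, 200, 50, 50, 50, 50, 50)
  sig_sox <- c(100, 50, 100, 100, 100, 800, 300, 100, 100, 100)
  signals <- list(
    mafb_gd13 = stats::setNames(sig_mafb, genes),
    pou5f1_gd13 = stats::setNames(sig_pou, genes),
    sox9_gd13 = stats::setNames(sig_sox, genes))

  on_3p <- !genes %in% "CARRY"
  annotation <- gene_annotation(
    genes, "none",
    presence = list(mogene_1_0_st = rep(TRUE, n),
                    mouse430_2 = on_3p, rat230a = on_3p, rat230_2 = on_3p))

  g3 <- genes[on_3p]
  fold3 <- function(full) full[on_3p]
  de <- list(
    mafb_gd13_vs_gd11 = make_de(
      genes,
      fold = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 3),
      q = c(0.2, 0.2, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.01),
      platform = "mogene_1_0_st"),
    whole_gd14_vs_gd11 = make_de(
      g3,
      fold = fold3(c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 0.9, 1.5, NA)),
      q = fold3(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, NA)),
      platform = "mouse430_2"),
    whole_gd14_vs_gd12 = make_de(
      g3,
      fold = fold3(c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 0.8, 1.2, NA)),
      q = fold3(c(0.4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.4, 0.1, NA)),
      platform = "mouse430_2"),
    rat_dbp = list(
      rat_acute = make_de(
        g3,
        fold = fold3(c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, NA)),
        q = fold3(c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, NA)),
        platform = "rat230a")),
    mouse_dbp = list(
      mouse_acute = make_de(
        g3,
        fold = fold3(c(1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 0.5, NA)),
        q = fold3(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.02, NA)),
        platform = "mouse430_2")),
    testis_vs_ovary = make_de(
      genes,
      fold = rep(3, n),
      q = rep(0.01, n),
      platform = "mogene_1_0_st"))
  list(de = de, signals = signals, annotation = annotation)
}
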