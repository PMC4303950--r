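# Deterministic desk-scale fixture with hand-computed expected values.

#' Write the deterministic test fixture
#'
#' A tiny, fully hand-checkable instance: 8 proteins over 3 compartments
#' (Nucleus, Cytoplasm, Membrane; one protein multi-localized, one with no
#' localization, two annotated via nested terms), 8 unique interactions
#' (plus one duplicate row and one row touching the unlocalized protein),
#' one all-PPI pathway stored as KGML and one non-PPI chain stored as a
#' reaction-list table. A sidecar JSON records the expected count matrix
#' `P`, efficiency matrix `E`, per-reaction efficiencies and pathway means
#' `Eff`, all computed by hand (plain fraction arithmetic), independent of
#' the package's counting code.
#'
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    localizations = file.path(dir, "localizations.tsv"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    mitab = file.path(dir, "interactions.mitab"),
    kgml = file.path(dir, "pathway_PW1.kgml"),
    reaction_list = file.path(dir, "pathways_nonppi.tsv"),
    classes = file.path(dir, "classes.tsv"),
    expected = file.path(dir, "expected.json"))

  writeLines(c("# protein_id\tterms",
               "p1\tNucleus",
               "p2\tnucleolus",
               "p3\tNucleus;Cytoplasm",
               "p4\tcytosol",
               "p5\tCytoplasm",
               "p6\tMembrane",
               "p7\tMembrane",
               "p8\t"), paths["localizations"])
  writeLines(c("# child\tparent",
               "nucleolus\tNucleus",
               "cytosol\tCytoplasm"), paths["hierarchy"])
  edge_rows <- c("p1\tp2", "p2\tp1", "p1\tp3", "p2\tp4", "p3\tp4",
                 "p3\tp5", "p6\tp7", "p5\tp6", "p1\tp8")
  writeLines(edge_rows, paths["interactions"])
  uniq <- c("p1\tp2", "p1\tp3", "p2\tp4", "p3\tp4", "p3\tp5", "p6\tp7",
            "p5\tp6", "p1\tp8")
  writeLines(c("#ID(s) interactor A\tID(s) interactor B",
               vapply(strsplit(uniq, "\t"), function(f)
                 sprintf("uniprotkb:%s\tuniprotkb:%s", f[1], f[2]), "")),
             paths["mitab"])

  pw1 <- pathway_document("PW1", list(
    reaction("p1", "p2"), reaction("p3", "p4"), reaction("p5", "p6")),
    title = "fixture ppi pathway")
  write_kgml(pw1, paths["kgml"])
  pw2 <- pathway_document("PW2", list(
    reaction("p1", kind = "non-ppi"),
    reaction("p4", kind = "non-ppi"),
    reaction("p6", kind = "non-ppi")))
  write_reaction_list(pw2, paths["reaction_list"])
  writeLines(c("PW1\tSignal transduction", "PW2\tMetabolism"),
             paths["classes"])

  # Hand arithmetic (fractions), recorded independently of the counting code:
  # memberships N={p1,p2,p3}, C={p3,p4,p5}, M={p6,p7} -> m = (3,3,2);
  # P(N,N)=2 (p1p2, p1p3), P(N,C)=4 (p1p3, p2p4, p3p4, p3p5),
  # P(C,C)=2 (p3p4, p3p5), P(M,M)=1 (p6p7), P(C,M)=1 (p5p6), P(N,M)=0;
  # E = P / (mi*mj).
  expected <- list(
    config = list(min_proteins = 1, term_delim = ";"),
    compartments = c("Nucleus", "Cytoplasm", "Membrane"),
    sizes = list(Nucleus = 3, Cytoplasm = 3, Membrane = 2),
    P = rbind(c(2, 4, 0), c(4, 2, 1), c(0, 1, 1)),
    E = rbind(c(2 / 9, 4 / 9, 0), c(4 / 9, 2 / 9, 1 / 6), c(0, 1 / 6, 1 / 4)),
    n_duplicates = 1,
    n_skipped_no_membership = 1,
    pathways = list(
      PW1 = list(
        reaction_efficiencies_mean = c(2 / 9, 1 / 3, 1 / 6),
        reaction_efficiencies_max = c(2 / 9, 4 / 9, 1 / 6),
        eff_mean = 13 / 54, eff_max = 5 / 18, n_scored = 3, n_skipped = 0),
      PW2 = list(
        reaction_efficiencies_mean = c(4 / 9, 1 / 6),
        eff_mean = 11 / 36, n_scored = 2, n_skipped = 0)))
  jsonlite::write_json(expected, paths["expected"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
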