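# Packaged worked examples: small documents built from the example
# sentences of the abstracts the method is usually demonstrated on (doc ids
# are their PubMed ids), with hand-encoded gold parses, protein mentions and
# gold coreference links. Used throughout the test suite; also convenient
# interactively:
#   fx <- packaged_examples()[["PMID-7964516"]]
#   resolve_document(fx$document, fx$sentences, preset_config("rb-full"))

#' Packaged example documents with gold parses
#'
#' Returns a named list of fixtures. Each fixture is a list with
#' `document` (a `coref_document` with gold links), `sentences` (gold
#' parse), `note`, and an `expect` list of per-stage expected outcomes used
#' by the test-suite (e.g. the antecedent the full system predicts and the
#' one an ablated system falls back to).
#'
#' @return Named list of fixtures.
#' @export
packaged_examples <- function() {
  out <- list()

  # -- workflow illustration: possessive "its" resolved to c-Myc ------------
  s1 <- sent_spec(
    tokens = list(
      tok("T", "NN"), tok("cell", "NN"), tok("hybridomas", "NNS", "hybridoma"),
      tok("respond", "VBP"), tok("to", "TO"), tok("activation", "NN"),
      tok("signals", "NNS", "signal"), tok("by", "IN"),
      tok("undergoing", "VBG", "undergo"), tok("apoptotic", "JJ"),
      tok("cell", "NN"), tok("death", "NN"), tok(",", ",", ",", glue = TRUE),
      tok("and", "CC"), tok("this", "DT"), tok("is", "VBZ", "be"),
      tok("likely", "JJ"), tok("to", "TO"), tok("represent", "VB"),
      tok("comparable", "JJ"), tok("events", "NNS", "event"),
      tok("related", "VBN", "relate"), tok("to", "TO"), tok("tolerance", "NN"),
      tok("induction", "NN"), tok("in", "IN"), tok("immature", "JJ"),
      tok("and", "CC"), tok("mature", "JJ"), tok("T", "NN"),
      tok("cells", "NNS", "cell"), tok("in", "FW"), tok("vivo", "FW"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(1, 3, 3), chk(6, 7, 7), chk(10, 12, 12),
                  chk(20, 25, 21), chk(27, 33, 31), chk(32, 33, 33)))
  s2 <- sent_spec(
    tokens = list(
      tok("Previous", "JJ", "previous"), tok("studies", "NNS", "study"),
      tok("using", "VBG", "use"), tok("antisense", "JJ"),
      tok("oligonucleotides", "NNS", "oligonucleotide"),
      tok("implicated", "VBD", "implicate"), tok("the", "DT"),
      tok("c-Myc", "NN", "c-Myc"), tok("protein", "NN"), tok("in", "IN"),
      tok("the", "DT"), tok("phenomenon", "NN"), tok("of", "IN"),
      tok("activation-induced", "JJ"), tok("apoptosis", "NN"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(1, 5, 2), chk(4, 5, 5), chk(7, 9, 9), chk(11, 15, 12),
                  chk(14, 15, 15)),
    proteins = list(c(8, 8)))
  s3 <- sent_spec(
    tokens = list(
      tok("This", "DT", "this"), tok("role", "NN"), tok("for", "IN"),
      tok("c-Myc", "NN", "c-Myc"), tok("in", "IN"), tok("apoptosis", "NN"),
      tok("is", "VBZ", "be"), tok("now", "RB"),
      tok("confirmed", "VBN", "confirm"), tok("in", "IN"),
      tok("studies", "NNS", "study"), tok("using", "VBG", "use"),
      tok("a", "DT"), tok("dominant", "JJ"), tok("negative", "JJ"),
      tok("form", "NN"), tok("of", "IN"), tok("its", "PRP$"),
      tok("heterodimeric", "JJ"), tok("binding", "NN"), tok("partner", "NN"),
      tok(",", ",", ",", glue = TRUE), tok("Max", "NN", "Max"),
      tok(",", ",", ",", glue = TRUE), tok("which", "WDT"), tok("we", "PRP"),
      tok("show", "VBP"), tok("here", "RB"), tok("inhibits", "VBZ", "inhibit"),
      tok("activation-induced", "JJ"), tok("apoptosis", "NN"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(
      chk(2, 2, 2),                       # role
      chk(2, 6, 2),                       # role for c-Myc in apoptosis
      chk(1, 6, 2),                       # This role for c-Myc in apoptosis
      chk(4, 4, 4),                       # c-Myc
      chk(6, 6, 6),                       # apoptosis
      chk(11, 11, 11),                    # studies
      chk(11, 31, 11, sub = TRUE),        # studies using ... apoptosis
      chk(13, 16, 16),                    # a dominant negative form
      chk(13, 23, 16),                    # a dominant negative form of ... Max
      chk(18, 21, 21),                    # its heterodimeric binding partner
      chk(23, 23, 23),                    # Max
      chk(30, 31, 31)),                   # activation-induced apoptosis
    edges = list(edg("prep-arg12", "chunk", 8, "chunk", 10),
                 edg("relative-arg", "chunk", 9, "token", 25)),
    proteins = list(c(4, 4), c(23, 23)))
  b <- build_document(
    "PMID-7964516", list(s1, s2, s3),
    links = list(
      list(anaphor = list(sent = 3, token = 18),
           antecedent = list(sent = 3, chunk = 4)),
      list(anaphor = list(sent = 3, token = 25),
           antecedent = list(sent = 3, chunk = 9))))
  b$note <- paste("Workflow illustration; 'its' must resolve to c-Myc under",
                  "the full rule set and to the nearer non-protein",
                  "'apoptosis' when the semantic constraint is off.")
  b$expect <- list(
    anaphors = c("this", "its", "which"),
    its_candidates_include = c("c-Myc", "apoptosis", "studies"),
    its_candidates_exclude = c("a dominant negative form of its heterodimeric binding partner, Max",
                               "this"),
    antecedent_full = "c-Myc", antecedent_no_rule2 = "apoptosis",
    markables_include = c("This role for c-Myc in apoptosis", "studies"),
    markables_exclude = "studies using a dominant negative form of its heterodimeric binding partner, Max, which we show here inhibits activation-induced apoptosis")
  out[["PMID-7964516"]] <- b

  # -- definite NP "this transcription factor" -> IRF-1 ---------------------
  s1 <- sent_spec(
    tokens = list(
      tok("Therefore", "RB"), tok(",", ",", ",", glue = TRUE),
      tok("IRF-1", "NN", "IRF-1"), tok("may", "MD"), tok("be", "VB"),
      tok("an", "DT"), tok("important", "JJ"), tok("contributor", "NN"),
      tok("to", "TO"), tok("IL-12", "NN", "IL-12"), tok("signaling", "NN"),
      tok(",", ",", ",", glue = TRUE), tok("and", "CC"), tok("we", "PRP"),
      tok("speculate", "VBP"), tok("that", "IN"), tok("the", "DT"),
      tok("defective", "JJ"), tok("IL-12", "NN", "IL-12"),
      tok("responses", "NNS", "response"), tok("seen", "VBN", "see"),
      tok("in", "IN"), tok("IRF-1-/-", "NN", "IRF-1-/-"),
      tok("mice", "NNS", "mouse"), tok("might", "MD"), tok("be", "VB"),
      tok("attributable", "JJ"), tok(",", ",", ",", glue = TRUE),
      tok("in", "IN"), tok("part", "NN"), tok(",", ",", ",", glue = TRUE),
      tok("to", "TO"), tok("the", "DT"), tok("absence", "NN"), tok("of", "IN"),
      tok("this", "DT"), tok("transcription", "NN"), tok("factor", "NN"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(
      chk(3, 3, 3),                        # IRF-1
      chk(6, 11, 8),                       # an important contributor to ...
      chk(10, 11, 11),                     # IL-12 signaling
      chk(17, 24, 20, sub = TRUE),         # the defective ... mice
      chk(17, 20, 20),                     # the defective IL-12 responses
      chk(23, 24, 24),                     # IRF-1-/- mice
      chk(30, 30, 30),                     # part
      chk(33, 38, 34),                     # the absence of this ... factor
      chk(36, 38, 38)),                    # this transcription factor
    proteins = list(c(3, 3), c(10, 10), c(19, 19)))
  b <- build_document(
    "PMID-10358173", list(s1),
    links = list(list(anaphor = list(sent = 1, chunk = 9),
                      antecedent = list(sent = 1, chunk = 1))))
  b$note <- paste("Without the protein semantic constraint the closest",
                  "number-agreeing candidate 'part' wins; with it the",
                  "closest protein candidate IRF-1 is selected.")
  b$expect <- list(anaphor = "this transcription factor",
                   antecedent_full = "IRF-1", antecedent_no_rule2 = "part")
  out[["PMID-10358173"]] <- b

  # -- possessive cued by "transactivation" ---------------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("This", "DT", "this"), tok("ability", "NN"), tok("of", "IN"),
      tok("CIITA", "NN", "CIITA"), tok("to", "TO"), tok("facilitate", "VB"),
      tok("promoter", "NN"), tok("occupation", "NN"), tok("is", "VBZ", "be"),
      tok("undissociable", "JJ"), tok("from", "IN"), tok("its", "PRP$"),
      tok("transactivation", "NN"), tok("potential", "NN"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(1, 8, 2), chk(4, 4, 4), chk(7, 8, 8), chk(12, 14, 14)),
    proteins = list(c(4, 4)))
  b <- build_document(
    "PMID-10221658", list(s1),
    links = list(list(anaphor = list(sent = 1, token = 12),
                      antecedent = list(sent = 1, chunk = 2))))
  b$note <- "'its transactivation potential' marks 'its' as a protein reference."
  b$expect <- list(its_sem = "PROTEIN", antecedent_full = "CIITA")
  out[["PMID-10221658"]] <- b

  # -- possessive cued by "sequence" ----------------------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("In", "IN"), tok("transient", "JJ"), tok("transfection", "NN"),
      tok("experiments", "NNS", "experiment"), tok(",", ",", ",", glue = TRUE),
      tok("BCL6", "NN", "BCL6"), tok("can", "MD"), tok("repress", "VB"),
      tok("transcription", "NN"), tok("from", "IN"),
      tok("promoters", "NNS", "promoter"), tok("linked", "VBN", "link"),
      tok("to", "TO"), tok("its", "PRP$"), tok("DNA", "NN", "DNA"),
      tok("target", "NN"), tok("sequence", "NN"), tok("and", "CC"),
      tok("this", "DT", "this"), tok("activity", "NN"), tok("is", "VBZ", "be"),
      tok("regulated", "VBN", "regulate"), tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(2, 4, 4), chk(6, 6, 6), chk(9, 9, 9),
                  chk(11, 17, 11, sub = TRUE), chk(11, 11, 11),
                  chk(14, 17, 17), chk(19, 20, 20)),
    proteins = list(c(6, 6)))
  b <- build_document(
    "PMID-8692924", list(s1),
    links = list(list(anaphor = list(sent = 1, token = 14),
                      antecedent = list(sent = 1, chunk = 2))))
  b$note <- "'its DNA target sequence' marks 'its' as a protein reference."
  b$expect <- list(its_sem = "PROTEIN", antecedent_full = "BCL6")
  out[["PMID-8692924"]] <- b

  # -- possessive cued by "binding"; long apposition ------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("Human", "JJ", "human"), tok("immunodeficiency", "NN"),
      tok("virus", "NN"), tok("type", "NN"), tok("1", "CD", "1"),
      tok("(", "-LRB-", "("), tok("HIV-1", "NN", "HIV-1", glue = TRUE),
      tok(")", "-RRB-", ")", glue = TRUE), tok("Tat", "NN", "Tat"),
      tok(",", ",", ",", glue = TRUE), tok("an", "DT"), tok("early", "JJ"),
      tok("regulatory", "JJ"), tok("protein", "NN"), tok("that", "WDT"),
      tok("is", "VBZ", "be"), tok("critical", "JJ"), tok("for", "IN"),
      tok("viral", "JJ"), tok("gene", "NN"), tok("expression", "NN"),
      tok("and", "CC"), tok("replication", "NN"), tok(",", ",", ",", glue = TRUE),
      tok("transactivates", "VBZ", "transactivate"), tok("the", "DT"),
      tok("HIV-1", "NN", "HIV-1"), tok("long", "JJ"), tok("terminal", "JJ"),
      tok("repeat", "NN"), tok("(", "-LRB-", "("),
      tok("LTR", "NN", "LTR", glue = TRUE), tok(")", "-RRB-", ")", glue = TRUE),
      tok("via", "IN"), tok("its", "PRP$"), tok("binding", "NN"),
      tok("to", "TO"), tok("the", "DT"), tok("transactivation", "NN"),
      tok("response", "NN"), tok("element", "NN"), tok("(", "-LRB-", "("),
      tok("TAR", "NN", "TAR", glue = TRUE), tok(")", "-RRB-", ")", glue = TRUE),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(
      chk(1, 9, 9),                        # Human ... (HIV-1) Tat
      chk(11, 23, 14, sub = TRUE),         # an early regulatory protein that ...
      chk(19, 23, 21),                     # viral gene expression and replication
      chk(26, 33, 30),                     # the HIV-1 long terminal repeat (LTR)
      chk(35, 44, 36),                     # its binding to ... (TAR)
      chk(38, 44, 41)),                    # the transactivation response element
    proteins = list(c(9, 9)))
  b <- build_document(
    "PMID-9261367", list(s1),
    links = list(list(anaphor = list(sent = 1, token = 35),
                      antecedent = list(sent = 1, chunk = 1))))
  b$note <- paste("Without the context cue the nearer 'the HIV-1 long",
                  "terminal repeat (LTR)' would win; 'binding' marks 'its'",
                  "as protein and the Tat noun phrase is selected.")
  b$expect <- list(its_sem = "PROTEIN",
                   antecedent_full = "Human immunodeficiency virus type 1 (HIV-1) Tat")
  out[["PMID-9261367"]] <- b

  # -- number-agreement violation in real data ------------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("A", "DT", "a"), tok("role", "NN"), tok("for", "IN"),
      tok("OTF-2", "NN", "OTF-2"), tok("in", "IN"), tok("DRA", "NN", "DRA"),
      tok("gene", "NN"), tok("transcription", "NN"), tok("was", "VBD", "be"),
      tok("proposed", "VBN", "propose"), tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(1, 8, 2), chk(4, 4, 4), chk(6, 8, 8)),
    proteins = list(c(4, 4), c(6, 6)))
  s2 <- sent_spec(
    tokens = list(
      tok("In", "IN"), tok("contrast", "NN"), tok(",", ",", ",", glue = TRUE),
      tok("OTF-1-enriched", "JJ"), tok("protein", "NN"),
      tok("fractions", "NNS", "fraction"), tok("did", "VBD", "do"),
      tok("not", "RB"), tok("affect", "VB"), tok("DRA", "NN", "DRA"),
      tok("gene", "NN"), tok("transcription", "NN"), tok("although", "IN"),
      tok("it", "PRP"), tok("functionally", "RB"),
      tok("enhanced", "VBD", "enhance"), tok("the", "DT"),
      tok("transcription", "NN"), tok("of", "IN"), tok("another", "DT"),
      tok("promoter", "NN"), tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(4, 6, 6), chk(10, 12, 12), chk(17, 21, 18),
                  chk(20, 21, 21)),
    edges = list(edg("prep-arg12", "chunk", 3, "chunk", 4)),
    proteins = list(c(10, 10)))
  b <- build_document(
    "PMID-1560002", list(s1, s2),
    links = list(list(anaphor = list(sent = 2, token = 14),
                      antecedent = list(sent = 2, chunk = 1))))
  b$note <- paste("The gold antecedent 'OTF-1-enriched protein fractions' is",
                  "plural while the anaphor 'it' is singular: number",
                  "agreement excludes the true antecedent, so the rule-based",
                  "prediction necessarily misses this link.")
  b$expect <- list(it_is_anaphoric = TRUE,
                   gold_antecedent = "OTF-1-enriched protein fractions",
                   gold_antecedent_number = "plural",
                   number_violation = TRUE)
  out[["PMID-1560002"]] <- b

  # -- antecedent with two protein mentions ---------------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("With", "IN"), tok("the", "DT"), tok("aim", "NN"), tok("of", "IN"),
      tok("identifying", "VBG", "identify"), tok("genetic", "JJ"),
      tok("targets", "NNS", "target"), tok("for", "IN"), tok("these", "DT"),
      tok("transcription", "NN"), tok("factors", "NNS", "factor"),
      tok(",", ",", ",", glue = TRUE), tok("we", "PRP"), tok("stably", "RB"),
      tok("transfected", "VBD", "transfect"), tok("cDNAs", "NNS", "cdna"),
      tok("encoding", "VBG", "encode"), tok("EBF", "NN", "EBF"),
      tok("or", "CC"), tok("a", "DT"), tok("covalent", "JJ"),
      tok("homodimer", "NN"), tok("of", "IN"), tok("E47", "NN", "E47"),
      tok(",", ",", ",", glue = TRUE), tok("into", "IN"),
      tok("Ba/F3", "NN", "Ba/F3"), tok("cells", "NNS", "cell"),
      tok(",", ",", ",", glue = TRUE), tok("which", "WDT"),
      tok("lack", "VBP"), tok("both", "DT"), tok("factors", "NNS", "factor"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(
      chk(2, 3, 3),                        # the aim
      chk(6, 11, 7),                       # genetic targets for these ...
      chk(9, 11, 11),                      # these transcription factors
      chk(16, 24, 16),                     # cDNAs encoding EBF or a ... E47
      chk(18, 18, 18),                     # EBF
      chk(20, 24, 22),                     # a covalent homodimer of E47
      chk(24, 24, 24),                     # E47
      chk(27, 28, 28),                     # Ba/F3 cells
      chk(32, 33, 33)),                    # both factors
    edges = list(edg("relative-arg", "chunk", 8, "token", 30)),
    proteins = list(c(18, 18), c(24, 24)))
  b <- build_document(
    "PMID-9252117", list(s1),
    links = list(
      list(anaphor = list(sent = 1, chunk = 9),
           antecedent = list(sent = 1, chunk = 4)),
      list(anaphor = list(sent = 1, token = 30),
           antecedent = list(sent = 1, chunk = 8)))) # which -> Ba/F3 cells
  b$note <- paste("'both factors' links to an antecedent containing two",
                  "protein mentions (EBF, E47): two protein links derive",
                  "from one expression link.")
  b$expect <- list(anaphor = "both factors", n_protein_links = 2L,
                   antecedent_full = "cDNAs encoding EBF or a covalent homodimer of E47")
  out[["PMID-9252117"]] <- b

  # -- coordinated multi-protein antecedent ---------------------------------
  s1 <- sent_spec(
    tokens = list(
      tok("In", "IN"), tok("granulocytic", "JJ"), tok("and", "CC"),
      tok("monocytic", "JJ"), tok("lineages", "NNS", "lineage"),
      tok(",", ",", ",", glue = TRUE), tok("transcription", "NN"),
      tok("factors", "NNS", "factor"), tok("from", "IN"), tok("several", "JJ"),
      tok("families", "NNS", "family"), tok("are", "VBP", "be"),
      tok("active", "JJ"), tok(",", ",", ",", glue = TRUE),
      tok("including", "VBG", "include"),
      tok("AML1/CBF", "NN", "AML1/CBF"), tok("beta", "NN"),
      tok(",", ",", ",", glue = TRUE), tok("C/EBP", "NN", "C/EBP"),
      tok(",", ",", ",", glue = TRUE), tok("Ets", "NN", "Ets"),
      tok(",", ",", ",", glue = TRUE), tok("c-Myb", "NN", "c-Myb"),
      tok(",", ",", ",", glue = TRUE), tok("HOX", "NN", "HOX"),
      tok(",", ",", ",", glue = TRUE), tok("and", "CC"),
      tok("MZF-1", "NN", "MZF-1"), tok(".", ".", ".", glue = TRUE)),
    chunks = list(
      chk(2, 5, 5),                        # granulocytic and monocytic lineages
      chk(7, 11, 8),                       # transcription factors from ...
      chk(10, 11, 11),                     # several families
      chk(16, 28, 28),                     # AML1/CBF beta, ..., and MZF-1
      chk(16, 17, 17), chk(19, 19, 19), chk(21, 21, 21), chk(23, 23, 23),
      chk(25, 25, 25)),
    proteins = list(c(16, 17), c(19, 19), c(21, 21), c(23, 23), c(25, 25),
                    c(28, 28)))
  s2 <- sent_spec(
    tokens = list(
      tok("Few", "JJ", "few"), tok("of", "IN"), tok("these", "DT"),
      tok("factors", "NNS", "factor"), tok("are", "VBP", "be"),
      tok("expressed", "VBN", "express"), tok("exclusively", "RB"),
      tok("in", "IN"), tok("myeloid", "JJ"), tok("cells", "NNS", "cell"),
      tok(".", ".", ".", glue = TRUE)),
    chunks = list(chk(3, 4, 4), chk(9, 10, 10)))
  b <- build_document(
    "PMID-9291089", list(s1, s2),
    links = list(list(anaphor = list(sent = 2, chunk = 1),
                      antecedent = list(sent = 1, chunk = 4))))
  b$note <- paste("A coordinated six-protein antecedent; with a correct",
                  "(gold) parse of the coordination the definite NP 'these",
                  "factors' resolves to the full coordinated noun phrase.")
  b$expect <- list(anaphor = "these factors", n_protein_links = 6L,
                   antecedent_full = "AML1/CBF beta, C/EBP, Ets, c-Myb, HOX, and MZF-1")
  out[["PMID-9291089"]] <- b

  out
}
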