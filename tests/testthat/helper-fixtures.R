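# Shared fixture builders. Tiny ontologies are written as OBO text and read
# back through parse_obo() so the parser is on the path of every test.

write_tmp_text <- function(lines, ext = ".obo") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

obo_term <- function(id, namespace = "cellular_component", is_a = character(),
                     part_of = character(), alt_id = character(),
                     obsolete = FALSE, extra = character()) {
  c("[Term]", paste0("id: ", id), paste0("name: term ", id),
    paste0("namespace: ", namespace),
    if (length(alt_id)) paste0("alt_id: ", alt_id),
    if (length(is_a)) paste0("is_a: ", is_a, " ! parent"),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    if (obsolete) "is_obsolete: true",
    extra, "")
}

# R root; A is_a R; B is_a R; C part_of A  (the worked-example ontology)
tiny_dag <- function() {
  parse_obo(write_tmp_text(c(
    "format-version: 1.2", "",
    obo_term("GO:0000001"),
    obo_term("GO:0000002", is_a = "GO:0000001"),
    obo_term("GO:0000003", is_a = "GO:0000001"),
    obo_term("GO:0000004", part_of = "GO:0000002"))))
}

random_world <- function(seed, n_terms = 30L, depth = 4L,
                         part_of_fraction = 0.3, n_genes = 40L,
                         term_count_range = c(1L, 5L), ...) {
  spec <- fixture_spec(n_terms = n_terms, depth = depth,
                       part_of_fraction = part_of_fraction,
                       n_genes = n_genes,
                       term_count_range = term_count_range,
                       seed = seed, ...)
  dag <- make_ontology(spec)
  ann <- make_annotations(dag, spec)
  list(spec = spec, dag = dag, annotations = ann$annotations,
       table = ann$table)
}

gene2go_lines <- function(rows) {
  hdr <- "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory"
  c(hdr, vapply(rows, paste, character(1), collapse = "\t"))
}
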