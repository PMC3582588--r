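# Shared fixture access and small construction shortcuts.

fixtures <- packaged_examples()

# write a fixture (or any document+links) as standoff files in a temp dir
write_standoff_tmp <- function(document, links = document$gold_links,
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  base <- file.path(dir, document$doc_id)
  writeLines(document$text, paste0(base, ".txt"))
  writeLines(sprintf("%s\tProtein %d %d\t%s", document$proteins$id,
                     document$proteins$start, document$proteins$end,
                     document$proteins$text), paste0(base, ".a1"))
  if (!is.null(links)) write_predictions(document, links, paste0(base, ".a2"))
  base
}

# one-row markable lookup by surface text
markable_named <- function(markables, text) {
  m <- markables[markables$text == text, , drop = FALSE]
  stopifnot(nrow(m) == 1L)
  m
}
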