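# Small hand-built fixtures used across test files.

make_note_df <- function(pid, nid, type, date, text) {
  data.frame(patient_id = pid, note_id = nid, note_type = type,
             date = as.Date(date), text = text, stringsAsFactors = FALSE)
}

# a toy two-patient corpus written to JSONL/CSV files
write_toy_corpus_files <- function(dir = tempfile()) {
  dir.create(dir)
  notes <- c(
    '{"patient_id":"P1","note_id":"P1-01","note_type":"radiology","date":"2020-01-05","text":"IMPRESSION:\\nThere is a mass in the left lung."}',
    '{"patient_id":"P1","note_id":"P1-02","note_type":"pathology","date":"2020-01-10","text":"FINAL DIAGNOSIS:\\nBiopsy reveals adenocarcinoma."}',
    '{"patient_id":"P2","note_id":"P2-01","note_type":"radiology","date":"2020-03-01","text":"Unremarkable screening examination."}')
  writeLines(notes, file.path(dir, "notes.jsonl"))
  reg <- paste(
    "patient_id,diagnosis_date,site,histology,clinical_T,clinical_N,clinical_M,pathologic_T,pathologic_N,pathologic_M,gender,ethnicity",
    "P1,2020-01-10,LUNG,ADENOCARCINOMA,2,0,0,,,,female,group_a",
    "P2,,,,,,,,,,male,group_b", sep = "\n")
  writeLines(reg, file.path(dir, "registry.csv"))
  dir
}

# build an AbstractionInstance directly from sentence texts (one note)
toy_instance <- function(texts, label, pid = "PX", attribute = "site",
                         note_id = "PX-01", date = as.Date("2020-01-01")) {
  toks <- lapply(texts, function(t) wordTokens_(t))
  offs <- cumsum(c(0L, nchar(texts) + 1L))[seq_along(texts)]
  new("AbstractionInstance", patient_id = pid, attribute = attribute,
      sentences = data.frame(
        note_id = note_id, note_type = "pathology", date = date,
        sentence_index = seq_along(texts) - 1L,
        start = offs, end = offs + nchar(texts), text = texts,
        tokens = I(toks), stringsAsFactors = FALSE),
      label = label)
}

wordTokens_ <- function(t) OncoAbstract:::wordTokens(t)$token

# linearly separable toy training set: label determined by one keyword
toy_separable_set <- function(n_per = 10L, attribute = "site") {
  insts <- list()
  for (i in seq_len(n_per)) {
    insts[[length(insts) + 1L]] <- toy_instance(
      c(sprintf("Report number %d follows.", i),
        "There is a mass in the lung."),
      "LUNG", pid = sprintf("A%02d", i), attribute = attribute)
    insts[[length(insts) + 1L]] <- toy_instance(
      c(sprintf("Report number %d follows.", i),
        "There is a mass in the liver."),
      "LIVER", pid = sprintf("B%02d", i), attribute = attribute)
  }
  insts
}

tiny_model_cfg <- function(labels, seed = 1L) {
  hierModelConfig(emb_dim = 16L, n_layers = 1L, n_heads = 2L, ffn_dim = 24L,
                  gru_hidden = 8L, attn_dim = 8L, max_tokens = 16L,
                  vocab_size = 200L, dropout = 0, lr = 5e-3,
                  batch_size = 4L, max_epochs = 50L, patience = 50L,
                  seed = seed)
}
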