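# Small in-code fixtures shared across tests.

make_bm <- function(values, group = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cg%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  ann <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  if (!is.null(group)) ann$group <- group
  extra <- list(...)
  for (k in names(extra)) ann[[k]] <- extra[[k]]
  beta_matrix(values, ann)
}

# A tiny locus table file in the supplementary layout.
write_locus_table <- function(ids, path, sep = ",") {
  df <- data.frame(IlluminaID = ids,
                   geneID = seq_along(ids),
                   symbol = paste0("G", seq_along(ids)),
                   MapInfo = seq_along(ids) * 100L,
                   chromosome = "1")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
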