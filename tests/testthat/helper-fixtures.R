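# shared helpers: tiny in-code fixtures written to tempfiles

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_matrix <- function(values, genes, samples, mode = "intensity") {
  m <- matrix(values, length(genes), length(samples), byrow = TRUE,
              dimnames = list(genes, samples))
  attr(m, "mode") <- mode
  m
}

write_tmp_matrix <- function(m, gene_col = "gene") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random two-group intensity matrix for oracle comparisons
random_toy_de <- function(n_genes = 30, n1 = 4, n2 = 5) {
  samples <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  m <- matrix(rnorm(n_genes * (n1 + n2)), n_genes, n1 + n2,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  attr(m, "mode") <- "intensity"
  list(matrix = m, group1 = samples[seq_len(n1)],
       group2 = samples[n1 + seq_len(n2)])
}
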