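# Shared fixture builders; everything is generated in code at test time.

# small random positive panel with arbitrary protein names
random_panel <- function(n, p, seed, ids = sprintf("s%02d", seq_len(n)),
                         proteins = sprintf("prot%02d", seq_len(p))) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p)), n, p, dimnames = list(ids, proteins))
  expression_panel(m)
}

# balanced labels for a panel
balanced_labels <- function(panel) {
  n <- length(panel$sample_ids)
  response_table(panel$sample_ids,
                 rep(c("synergistic", "low"), length.out = n))
}

# write a small delimited fixture and return its path (tempdir-scoped)
write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent loop-based oracle for synergy scoring: re-derives every
# combination score cell by cell from the raw condition table
oracle_scores <- function(grid) {
  cond <- grid$conditions
  out <- NULL
  for (i in seq_len(nrow(cond))) {
    a <- cond$dose_a[i]; b <- cond$dose_b[i]
    if (a > 0 && b > 0) {
      f_a <- cond$f_dead[cond$dose_a == a & cond$dose_b == 0]
      f_b <- cond$f_dead[cond$dose_a == 0 & cond$dose_b == b]
      f_exp <- f_a + f_b - f_a * f_b
      out <- rbind(out, data.frame(dose_a = a, dose_b = b,
                                   score = cond$f_dead[i] - f_exp))
    }
  }
  out
}
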