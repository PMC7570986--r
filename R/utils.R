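# Internal helpers shared across modules.

# Signal a validation error (bad user input / malformed data). These map to
# CLI exit status 1; everything else maps to status 2.
fs_validation_error <- function(msg) {
  stop(structure(
    class = c("fluorsep_validation_error", "fluorsep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fs_computation_error <- function(msg) {
  stop(structure(
    class = c("fluorsep_computation_error", "fluorsep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Number of connected components of an undirected graph given as a logical
# adjacency matrix (diagonal ignored). Union-find; n here is tiny (<= number
# of samples) so no graph library is warranted.
n_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && isTRUE(adj[i, j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Fixed-precision number formatting for byte-stable CSV output.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_table_stable <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
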