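# Shared simulated-study fixtures, built once per test run.
#
# study_corpus(): ~500 patterns over the six symmetry classes (no broken
# variants) with their full 24-predictor table at 48 x 48 rendering.
# contrast_corpus(): smaller symmetric/asymmetric corpus *with* broken
# variants, for the broken-symmetry contrasts.

.fixture_cache <- new.env(parent = emptyenv())

corpus_with_predictors <- function(key, n_per_class, classes, broken,
                                   px = 6L, seed = 20170101L) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  corp <- generate_corpus(n_per_class = n_per_class, classes = classes,
                          broken = broken, px_per_cell = px, seed = seed)
  preds <- lapply(names(corp$images), function(id)
    data.frame(stimulus = id, t(extract_all(corp$images[[id]])),
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, preds)
  res <- list(corpus = corp, table = tab, meta = corp$meta)
  .fixture_cache[[key]] <- res
  res
}

study_corpus <- function() {
  corpus_with_predictors(
    "study", n_per_class = 84L,
    classes = c("asymmetric", "1-orthogonal", "2-orthogonal",
                "1-diagonal", "2-diagonal", "4-axes"),
    broken = FALSE)
}

contrast_corpus <- function() {
  corpus_with_predictors(
    "contrast", n_per_class = 24L,
    classes = c("asymmetric", "4-axes"),
    broken = TRUE, seed = 20170202L)
}

# Standardized predictor table (24 columns) plus stimulus ids and MSA20.
standardized_table <- function(fix) {
  tab <- fix$table
  tab$MSA20 <- 100 * rowMeans(as.matrix(tab[, c("MSA", "MSB", "MSC", "MSD")])^20)
  z <- zstandardize(tab[c(PREDICTOR_NAMES, "MSA20")])
  z$stimulus <- tab$stimulus
  z
}
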