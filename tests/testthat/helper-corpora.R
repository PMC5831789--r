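# study-scale corpora are expensive; build each once per test run
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(noise, seed) {
  key <- sprintf("n%03d_s%d", round(noise * 100), seed)
  if (is.null(.corpus_cache[[key]])) {
    corp <- generate_binding_corpus(synthetic_spec(noise = noise, seed = seed))
    .corpus_cache[[key]] <- list(corpus = corp, dataset = corpus_dataset(corp))
  }
  .corpus_cache[[key]]
}
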