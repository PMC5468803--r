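# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# pure tone segment
make_tone <- function(freq = 440, dur = 1, fs = 8000, amp = 0.5,
                      label = "music", id = "tone") {
  t <- seq_len(round(dur * fs)) / fs
  audio_segment(amp * sin(2 * pi * freq * t), fs, label = label, id = id)
}

# quarter-scale synthetic corpus (11 falls + 11 nonfalls per set)
tiny_corpus <- function() {
  cached("tiny_corpus", function() {
    gen_corpus(scene_config(scale = 0.25, seed = 11))
  })
}

tiny_frontend <- function() {
  cached("tiny_frontend", function() {
    prepare_frontend(tiny_corpus(), J = 4, seed = 5)
  })
}

# detector fitted on the tiny corpus, validated on half of set 3
tiny_detector <- function() {
  cached("tiny_detector", function() {
    corpus <- tiny_corpus()
    man <- corpus$sets$set3$manifest
    val_idx <- c(which(man$is_fall)[1:5], which(!man$is_fall)[1:5])
    fall_detector(normal = corpus$train,
                  object_candidates = corpus$object_pool$clean,
                  background_pool = corpus$background_pool$clean,
                  validation = corpus$sets$set3$clean[val_idx],
                  J = 4, nu = 0.2, gamma = 2^-9, seed = 5)
  })
}

# hand-built diagonal GMM (for contract tests that need no EM run)
fake_ubm <- function(J, D, seed = 1) {
  with_seed <- get("with_seed", envir = asNamespace("acufall"))
  with_seed(seed, structure(
    list(weights = rep(1 / J, J),
         means = matrix(rnorm(J * D, sd = 2), J, D),
         vars = matrix(runif(J * D, 0.5, 2), J, D),
         J = J, D = D, loglik_trace = numeric(0)),
    class = "gmm_ubm"))
}

# one-class SVM stub with a fixed decision sign everywhere
fake_ocsvm <- function(dim, sign = -1L) {
  structure(list(sv = matrix(0, 1, dim), alpha = 1,
                 rho = if (sign < 0) 2 else -2,
                 gamma = 1, nu = 0.5, l = 1, center = NULL, scale = NULL),
            class = "ocsvm_model")
}
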