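#' Attribute vocabulary for botanical drugs
#'
#' The fixed, ordered vocabulary used to encode herbs: ten property/flavor
#' tokens followed by twelve meridian-tropism tokens, 22 in total. The order
#' is part of the data contract and is persisted alongside any feature
#' matrix derived from it.
#'
#' @return A list with elements `properties_flavors` (10 tokens),
#'   `meridians` (12 tokens), `tokens` (their concatenation) and `n` (22).
#' @export
#' @examples
#' v <- attribute_vocabulary()
#' v$n
attribute_vocabulary <- function() {
  pf <- c("cold", "hot", "warm", "cool", "neutral",
          "sour", "bitter", "sweet", "pungent", "salty")
  mer <- c("lung", "pericardium", "heart", "large intestine",
           "triple energizer", "small intestine", "stomach", "gallbladder",
           "bladder", "spleen", "liver", "kidney")
  list(properties_flavors = pf, meridians = mer,
       tokens = c(pf, mer), n = length(pf) + length(mer))
}

#' Encode a herb's attributes as a multi-hot vector
#'
#' Each attribute token maps to a one-hot indicator over the fixed
#' vocabulary; a herb's feature is the union (multi-hot) of its attribute
#' indicators.
#'
#' @param attributes Character vector of vocabulary tokens (may be empty,
#'   which yields a zero vector with a warning).
#' @param vocab Vocabulary as returned by [attribute_vocabulary()].
#' @return Named binary integer vector of length `vocab$n`.
#' @export
#' @examples
#' encode_herb(c("cold", "sweet", "liver"))
encode_herb <- function(attributes, vocab = attribute_vocabulary()) {
  attributes <- attributes[!is.na(attributes) & nzchar(attributes)]
  unknown <- setdiff(attributes, vocab$tokens)
  if (length(unknown))
    stop("unknown attribute token(s): ", paste(unknown, collapse = ", "))
  y <- integer(vocab$n)
  names(y) <- vocab$tokens
  if (!length(attributes)) {
    warning("herb has no attributes; returning zero vector")
    return(y)
  }
  y[match(unique(attributes), vocab$tokens)] <- 1L
  y
}

#' Aggregate herb vectors into a standardized prescription feature
#'
#' The prescription feature is the elementwise sum of its herbs' attribute
#' vectors, standardized across its entries: `z = (s - mean(s)) / popsd(s)`
#' with the population (1/n) standard deviation. A constant sum vector
#' (popsd 0) yields a zero vector with a warning so batch pipelines keep
#' running.
#'
#' @param herb_vectors A list of equal-length numeric vectors, or a matrix
#'   with one herb per row.
#' @return Numeric vector with mean 0 and population sd 1 (or all zeros in
#'   the degenerate case).
#' @export
#' @examples
#' aggregate_prescription(list(c(1, 0, 1, 0), c(0, 1, 1, 0)))
aggregate_prescription <- function(herb_vectors) {
  if (is.list(herb_vectors)) {
    if (!length(herb_vectors)) stop("herb_vectors must be non-empty")
    lens <- lengths(herb_vectors)
    if (length(unique(lens)) != 1L) stop("herb vectors must all have the same length")
    s <- Reduce(`+`, lapply(herb_vectors, as.numeric))
  } else {
    m <- as.matrix(herb_vectors)
    if (!nrow(m)) stop("herb_vectors must be non-empty")
    s <- colSums(m)
  }
  sdev <- pop_sd(s)
  if (sdev == 0) {
    warning("constant summed feature (population sd 0); returning zero vector")
    return(s * 0)
  }
  (s - mean(s)) / sdev
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with nonzero norm.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have the same length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero-norm input")
  sum(u * v) / (nu * nv)
}

#' In-batch contrastive (SimCSE-style) loss
#'
#' For paired encodings `H` and `Hp` of the same strings under independent
#' dropout masks, the loss for row i is the cross-entropy of picking its own
#' partner among all rows of `Hp` under temperature-scaled cosine
#' similarity; the value returned is the mean over rows.
#'
#' @param H,Hp Numeric matrices of identical shape (N x d), rows nonzero.
#' @param tau Temperature, > 0.
#' @return Scalar loss, >= 0.
#' @export
simcse_loss <- function(H, Hp, tau = 0.05) {
  H <- as.matrix(H); Hp <- as.matrix(Hp)
  if (!identical(dim(H), dim(Hp))) stop("H and Hp must have identical shapes")
  if (tau <= 0) stop("tau must be > 0")
  nr <- sqrt(rowSums(H^2)); np <- sqrt(rowSums(Hp^2))
  if (any(nr == 0) || any(np == 0)) stop("rows must have nonzero norm")
  S <- (H / nr) %*% t(Hp / np) / tau
  P <- softmax_rows(S)
  mean(-log(pmax(diag(P), 1e-12)))
}

#' Sequence embedding specification
#'
#' Contract for pluggable sequence encoders (SMILES strings and protein
#' sequences share it): a fixed output dimension and determinism given
#' `(string, seed)`.
#'
#' @param dim Embedding length (default 256).
#' @param temperature Contrastive temperature, > 0.
#' @param dropout_rate Dropout rate in `[0, 1)` used to form positive pairs.
#' @param encoder_id Identifier of the encoder backend.
#' @param seed Integer seed (selects the hash salt of the default encoder).
#' @return A list of class `seq_embedding_spec`.
#' @export
sequence_embedding_spec <- function(dim = 256L, temperature = 0.05,
                                    dropout_rate = 0.1, encoder_id = "kmer",
                                    seed = 1L) {
  stopifnot(dim >= 1, temperature > 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(dim = as.integer(dim), temperature = temperature,
                 dropout_rate = dropout_rate, encoder_id = encoder_id,
                 seed = as.integer(seed)),
            class = "seq_embedding_spec")
}

#' Default deterministic character k-mer encoder
#'
#' Hashes overlapping character k-mers into `dim` buckets (seeded salt),
#' counts them and L2-normalizes, giving a lightweight deterministic
#' sequence featurizer. Strings shorter than `k` fall back to unigram
#' hashing.
#'
#' @param dim Output dimension.
#' @param k k-mer length.
#' @param seed Hash salt; the same string and seed always give the same row.
#' @return A function `f(strings)` returning an N x dim matrix.
#' @export
kmer_encoder <- function(dim = 256L, k = 3L, seed = 1L) {
  force(dim); force(k); force(seed)
  function(strings) {
    out <- matrix(0, length(strings), dim)
    for (i in seq_along(strings)) {
      s <- strings[[i]]
      if (is.na(s) || !nzchar(s)) stop("cannot embed an empty string (index ", i, ")")
      kk <- min(k, nchar(s))
      kmers <- substring(s, seq_len(nchar(s) - kk + 1L),
                         seq_len(nchar(s) - kk + 1L) + kk - 1L)
      b <- hash_bucket(kmers, dim, salt = seed)
      cnt <- tabulate(b, dim)
      out[i, ] <- cnt / sqrt(sum(cnt^2))
    }
    out
  }
}

#' Embed a batch of sequences with a pluggable encoder
#'
#' Deduplicates strings before encoding so identical inputs are guaranteed
#' identical rows, then validates the encoder contract (output dimension,
#' finite entries).
#'
#' @param strings Character vector (SMILES or protein sequences).
#' @param spec A [sequence_embedding_spec()].
#' @param encoder Optional encoder function; defaults to
#'   [kmer_encoder()] configured from `spec`.
#' @return N x dim numeric matrix, one row per input string.
#' @export
embed_sequences <- function(strings, spec = sequence_embedding_spec(),
                            encoder = NULL) {
  if (is.null(encoder)) encoder <- kmer_encoder(spec$dim, seed = spec$seed)
  uniq <- unique(strings)
  M <- encoder(uniq)
  if (!is.matrix(M) || nrow(M) != length(uniq))
    stop("encoder must return one row per string")
  if (ncol(M) != spec$dim)
    stop("encoder output dim ", ncol(M), " does not match spec dim ", spec$dim)
  if (!all(is.finite(M))) stop("encoder produced non-finite values")
  M[match(strings, uniq), , drop = FALSE]
}

#' Contrastively fine-tune a linear projection over an encoder
#'
#' Optional refinement of the default encoder: a square projection W is
#' trained with the in-batch contrastive objective, using two independent
#' dropout corruptions of each base embedding as the positive pair.
#' Returns an encoder honoring the same contract.
#'
#' @param strings Training corpus.
#' @param spec A [sequence_embedding_spec()].
#' @param epochs Training epochs (full batch).
#' @param lr Adam learning rate.
#' @return A list with the fine-tuned `encoder` function, the projection
#'   `W`, and the per-epoch `loss` trace.
#' @export
fit_simcse_projection <- function(strings, spec = sequence_embedding_spec(),
                                  epochs = 50L, lr = 1e-2) {
  base <- kmer_encoder(spec$dim, seed = spec$seed)
  X <- embed_sequences(strings, spec, base)
  with_seed(spec$seed, {
    params <- list(W = diag(spec$dim) + glorot(spec$dim, spec$dim) * 0.1)
    opt <- make_adam(lr = lr)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      tape <- new_tape()
      pn <- ad_params(tape, params)
      xin <- ad_input(tape, X)
      h1 <- ad_mm(tape, ad_dropout(tape, xin, spec$dropout_rate), pn$W)
      h2 <- ad_mm(tape, ad_dropout(tape, xin, spec$dropout_rate), pn$W)
      S <- ad_mm(tape, ad_l2norm_rows(tape, h1), ad_l2norm_rows(tape, h2),
                 transpose_b = TRUE)
      loss <- ad_cross_entropy(tape, ad_scale(tape, S, 1 / spec$temperature),
                               seq_len(nrow(X)))
      ad_backward(tape, loss)
      trace[ep] <- ad_value(loss)[1, 1]
      params <- opt(params, ad_grads(pn))
    }
    W <- params$W
    list(encoder = function(strings) embed_sequences(strings, spec, base) %*% W,
         W = W, loss = trace)
  })
}
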