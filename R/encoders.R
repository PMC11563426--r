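# Composition-based feature encoders. Every encoder is a pure function from
# a residue string to a fixed-length named numeric vector; names follow the
# "<ENCODER>.<key>" convention so column identity is stable across runs.

seq_chars <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  strsplit(residues, "", fixed = TRUE)[[1L]]
}

# k-mers of the canonical alphabet in row-major canonical order: AA, AC, ...
canonical_kmers <- function(k) {
  if (k == 1L) return(AA_ALPHABET)
  grid <- expand.grid(rep(list(AA_ALPHABET), k),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 canonical residues: component *i* is
#' count(residue *i*) / L. Components sum to 1.
#'
#' @param residues Residue string over the canonical alphabet.
#' @return Named numeric vector of length 20 (`AAC.A` ... `AAC.Y`).
#' @examples
#' encode_aac("RPFERDISNVPFS")
#' @export
encode_aac <- function(residues) {
  ch <- seq_chars(residues)
  v <- table(factor(ch, levels = AA_ALPHABET)) / length(ch)
  stats::setNames(as.numeric(v), paste0("AAC.", AA_ALPHABET))
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each ordered adjacent residue pair: count(ab) / (L - 1).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (`DPC.AA` ... `DPC.YY`).
#' @export
encode_dpc <- function(residues) {
  ch <- seq_chars(residues)
  L <- length(ch)
  if (L < 2L) stop("dipeptide composition needs length >= 2")
  pairs <- paste0(ch[-L], ch[-1L])
  keys <- canonical_kmers(2L)
  v <- table(factor(pairs, levels = keys)) / (L - 1L)
  stats::setNames(as.numeric(v), paste0("DPC.", keys))
}

#' Tripeptide composition (TPC)
#'
#' Frequency of each ordered adjacent residue triple: count(abc) / (L - 2).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 8000.
#' @export
encode_tpc <- function(residues) {
  ch <- seq_chars(residues)
  L <- length(ch)
  if (L < 3L) stop("tripeptide composition needs length >= 3")
  triples <- paste0(ch[1:(L - 2L)], ch[2:(L - 1L)], ch[3:L])
  keys <- canonical_kmers(3L)
  v <- table(factor(triples, levels = keys)) / (L - 2L)
  stats::setNames(as.numeric(v), paste0("TPC.", keys))
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For every gap g in 0..`gap_max` and every ordered residue pair (a, b),
#' the frequency of positions i with residue a at i and residue b at
#' i + g + 1, normalised by the number of such position pairs (L - g - 1).
#' Each gap block therefore sums to 1. With the default `gap_max = 3` the
#' vector has 4 x 400 = 1600 components.
#'
#' @inheritParams encode_aac
#' @param gap_max Largest gap considered (default 3).
#' @return Named numeric vector of length `400 * (gap_max + 1)`
#'   (`CKSAAP.g0.AA`, ..., `CKSAAP.g3.YY`).
#' @export
encode_cksaap <- function(residues, gap_max = 3L) {
  ch <- seq_chars(residues)
  L <- length(ch)
  stopifnot(gap_max >= 0L)
  if (L < gap_max + 2L) {
    stop("sequence too short for gap_max = ", gap_max,
         " (needs length >= ", gap_max + 2L, ")")
  }
  keys <- canonical_kmers(2L)
  blocks <- lapply(0:gap_max, function(g) {
    n <- L - g - 1L
    pairs <- paste0(ch[1:n], ch[(1:n) + g + 1L])
    v <- table(factor(pairs, levels = keys)) / n
    stats::setNames(as.numeric(v), paste0("CKSAAP.g", g, ".", keys))
  })
  do.call(c, blocks)
}

# Sequence-order correlation for pseudo amino-acid composition:
# squared-difference correlation averaged over the standardised property set.
paac_theta <- function(ch, lambda, props) {
  L <- length(ch)
  vapply(seq_len(lambda), function(d) {
    i <- seq_len(L - d)
    corr <- rowMeans(vapply(props, function(p) (p[ch[i + d]] - p[ch[i]])^2,
                            numeric(L - d)))
    mean(corr)
  }, numeric(1))
}

#' Pseudo amino-acid composition (PAAC)
#'
#' Chou's pseudo amino-acid composition: the 20 residue frequencies
#' augmented with `lambda` sequence-order correlation factors computed from
#' standardised hydrophobicity, hydrophilicity and side-chain-mass tables
#' (see [paac_properties()]). All 20 + lambda components share the
#' denominator 1 + w * sum(theta), so the vector sums to 1.
#' With `lambda = 0` the encoder reduces exactly to [encode_aac()].
#'
#' @inheritParams encode_aac
#' @param lambda Number of sequence-order tiers (default 2; requires
#'   L > lambda).
#' @param w Weight blending composition and sequence-order terms
#'   (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
encode_paac <- function(residues, lambda = 2L, w = 0.05) {
  ch <- seq_chars(residues)
  L <- length(ch)
  stopifnot(lambda >= 0L, w >= 0)
  if (L <= lambda) stop("pseudo composition needs length > lambda = ", lambda)
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET))) / L
  if (lambda == 0L) {
    return(stats::setNames(f, paste0("PAAC.", AA_ALPHABET)))
  }
  props <- lapply(paac_properties(), standardize_property)
  theta <- paac_theta(ch, lambda, props)
  denom <- 1 + w * sum(theta)
  stats::setNames(c(f / denom, w * theta / denom),
                  c(paste0("PAAC.", AA_ALPHABET),
                    paste0("PAAC.lambda", seq_len(lambda))))
}

#' Amphiphilic pseudo amino-acid composition (APAAC)
#'
#' The amphiphilic variant of pseudo amino-acid composition: the 20 residue
#' frequencies plus `2 * lambda` sequence-order factors from two separate
#' correlation chains — products of standardised hydrophobicity values and of
#' standardised hydrophilicity values at each lag. Components share the
#' denominator 1 + w * sum(tau). `lambda = 0` reduces to [encode_aac()].
#'
#' @inheritParams encode_paac
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
encode_apaac <- function(residues, lambda = 2L, w = 0.05) {
  ch <- seq_chars(residues)
  L <- length(ch)
  stopifnot(lambda >= 0L, w >= 0)
  if (L <= lambda) stop("pseudo composition needs length > lambda = ", lambda)
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET))) / L
  if (lambda == 0L) {
    return(stats::setNames(f, paste0("APAAC.", AA_ALPHABET)))
  }
  pr <- paac_properties()
  h1 <- standardize_property(pr$hydrophobicity)
  h2 <- standardize_property(pr$hydrophilicity)
  tau <- unlist(lapply(seq_len(lambda), function(d) {
    i <- seq_len(L - d)
    c(mean(h1[ch[i]] * h1[ch[i + d]]),
      mean(h2[ch[i]] * h2[ch[i + d]]))
  }))
  denom <- 1 + w * sum(tau)
  stats::setNames(c(f / denom, w * tau / denom),
                  c(paste0("APAAC.", AA_ALPHABET),
                    paste0("APAAC.", rep(c("hb", "hl"), lambda),
                           ".lambda", rep(seq_len(lambda), each = 2))))
}

#' CTD composition (CTDC)
#'
#' Composition part of the composition/transition/distribution descriptor
#' family: for each of 13 physicochemical properties the residues are
#' partitioned into three groups, and the feature is each group's frequency
#' in the sequence. Each property block of three features sums to 1, giving
#' 13 x 3 = 39 components.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 39
#'   (`CTDC.<property>.G1` ... `CTDC.<property>.G3`).
#' @export
encode_ctdc <- function(residues) {
  ch <- seq_chars(residues)
  L <- length(ch)
  groups <- ctd_groups()
  out <- unlist(lapply(names(groups), function(prop) {
    g <- groups[[prop]]
    v <- vapply(g, function(members) sum(ch %in% members) / L, numeric(1))
    stats::setNames(v, paste0("CTDC.", prop, ".G", 1:3))
  }))
  out
}

#' Conjoint triad composition
#'
#' Residues are mapped to 7 classes by the standard conjoint-triad grouping
#' (dipole and side-chain-volume clusters), then every sliding window of 3
#' consecutive class labels is counted into one of 7^3 = 343 bins. By
#' default the raw counts are min-max scaled to \[0, 1\] across the bins
#' ((count - min) / max, the descriptor's original normalisation);
#' `normalize = "frequency"` divides counts by the window count L - 2
#' instead.
#'
#' @inheritParams encode_aac
#' @param normalize `"minmax"` (default) or `"frequency"`.
#' @return Named numeric vector of length 343 (`CTriad.c1c1c1` ...).
#' @export
encode_ctriad <- function(residues, normalize = c("minmax", "frequency")) {
  normalize <- match.arg(normalize)
  ch <- seq_chars(residues)
  L <- length(ch)
  if (L < 3L) stop("conjoint triad needs length >= 3")
  classes <- ctriad_classes()
  cls_of <- integer(0)
  for (k in seq_along(classes)) cls_of[classes[[k]]] <- k
  lab <- cls_of[ch]
  tri <- paste0("c", lab[1:(L - 2L)], "c", lab[2:(L - 1L)], "c", lab[3:L])
  grid <- expand.grid(1:7, 1:7, 1:7, KEEP.OUT.ATTRS = FALSE)
  keys <- paste0("c", grid[[3]], "c", grid[[2]], "c", grid[[1]])
  counts <- as.numeric(table(factor(tri, levels = keys)))
  v <- switch(normalize,
    minmax = if (max(counts) > 0) (counts - min(counts)) / max(counts) else counts,
    frequency = counts / (L - 2L))
  stats::setNames(v, paste0("CTriad.", keys))
}

#' Moran autocorrelation
#'
#' Moran spatial autocorrelation of standardised residue property values
#' along the chain at lags 1..`nlag`:
#' \deqn{I(d) = \frac{\frac{1}{L-d}\sum_i (x_i - \bar x)(x_{i+d} - \bar x)}
#'             {\frac{1}{L}\sum_i (x_i - \bar x)^2}}
#' where \eqn{\bar x} is the mean property value over the sequence. The
#' default is a single property (hydrophobicity) with `nlag = 2`, giving a
#' length-2 vector. Zero-variance sequences (homopolymers) return 0 at every
#' lag by convention.
#'
#' @inheritParams encode_aac
#' @param nlag Largest lag (default 2; requires L > nlag).
#' @param properties Character vector of property names from
#'   [paac_properties()] (default `"hydrophobicity"`).
#' @return Named numeric vector of length `nlag * length(properties)`.
#' @export
encode_moran <- function(residues, nlag = 2L, properties = "hydrophobicity") {
  ch <- seq_chars(residues)
  L <- length(ch)
  stopifnot(nlag >= 1L, length(properties) >= 1L)
  if (L <= nlag) stop("Moran autocorrelation needs length > nlag = ", nlag)
  tabs <- paac_properties()
  miss <- setdiff(properties, names(tabs))
  if (length(miss)) stop("unknown property: ", paste(miss, collapse = ", "))
  out <- unlist(lapply(properties, function(pn) {
    p <- standardize_property(tabs[[pn]])
    x <- p[ch]
    xbar <- mean(x)
    denom <- mean((x - xbar)^2)
    v <- vapply(seq_len(nlag), function(d) {
      if (denom == 0) return(0)
      i <- seq_len(L - d)
      mean((x[i] - xbar) * (x[i + d] - xbar)) / denom
    }, numeric(1))
    stats::setNames(v, paste0("Moran.", pn, ".lag", seq_len(nlag)))
  }))
  out
}

#' Reduced amino-acid cluster composition
#'
#' Maps residues to the clusters of a reduced alphabet (see [raac_scheme()])
#' and returns the cluster frequencies; components sum to 1. The default
#' four-cluster scheme gives a length-4 vector.
#'
#' @inheritParams encode_aac
#' @param scheme Cluster scheme identifier passed to [raac_scheme()].
#' @return Named numeric vector, one component per cluster
#'   (`RAACC.<cluster>`).
#' @export
encode_raacc <- function(residues, scheme = "four") {
  ch <- seq_chars(residues)
  cl <- raac_scheme(scheme)
  v <- vapply(cl, function(members) sum(ch %in% members) / length(ch),
              numeric(1))
  stats::setNames(v, paste0("RAACC.", names(cl)))
}

#' The encoder registry
#'
#' Maps encoder names to their functions and default parameters. Encoder
#' names are the keys accepted by [encode_dataset()] and the command-line
#' front end. Default parameters give the standard vector lengths:
#' AAC 20, DPC 400, TPC 8000, CKSAAP 1600, PAAC 22, APAAC 24, CTDC 39,
#' CTriad 343, Moran 2, RAACC 4.
#'
#' @return Named list; each element has `fn` (the encoder function) and
#'   `params` (named list of default parameters).
#' @export
encoder_registry <- function() {
  list(
    AAC    = list(fn = encode_aac,    params = list()),
    DPC    = list(fn = encode_dpc,    params = list()),
    TPC    = list(fn = encode_tpc,    params = list()),
    CKSAAP = list(fn = encode_cksaap, params = list(gap_max = 3L)),
    PAAC   = list(fn = encode_paac,   params = list(lambda = 2L, w = 0.05)),
    APAAC  = list(fn = encode_apaac,  params = list(lambda = 2L, w = 0.05)),
    CTDC   = list(fn = encode_ctdc,   params = list()),
    CTriad = list(fn = encode_ctriad, params = list(normalize = "minmax")),
    Moran  = list(fn = encode_moran,
                  params = list(nlag = 2L, properties = "hydrophobicity")),
    RAACC  = list(fn = encode_raacc,  params = list(scheme = "four"))
  )
}

# Minimum sequence length required by an encoder under given params.
encoder_min_length <- function(name, params) {
  switch(name,
    AAC = 1L, CTDC = 1L, RAACC = 1L,
    DPC = 2L, TPC = 3L, CTriad = 3L,
    CKSAAP = (params$gap_max %||% 3L) + 2L,
    PAAC = (params$lambda %||% 2L) + 1L,
    APAAC = (params$lambda %||% 2L) + 1L,
    Moran = (params$nlag %||% 2L) + 1L,
    1L)
}

#' Encode a peptide dataset into a feature matrix
#'
#' Applies one or more encoders to every sequence and concatenates the
#' per-encoder blocks column-wise in the order given. Row order equals
#' dataset order; row names are the peptide ids; column names carry the
#' encoder prefix (e.g. `AAC.A`, `DPC.AC`). The default combined feature
#' set used by the modelling layer is `c("AAC", "DPC")` (420 columns).
#'
#' @param d A [peptide_dataset].
#' @param encoders Character vector of registry names, or a named list
#'   mapping registry names to parameter overrides
#'   (e.g. `list(CKSAAP = list(gap_max = 2))`).
#' @return Numeric matrix, rows = peptides, columns = named features, with
#'   attribute `encoder_spec` recording the encoders and parameters used.
#' @examples
#' d <- peptide_dataset(c("p1", "n1"),
#'                      c("RPFERDISNVPFS", "SHLVEALYLVAGERG"), c(1, 0))
#' dim(encode_dataset(d, "AAC"))   # 2 x 20
#' @export
encode_dataset <- function(d, encoders = c("AAC", "DPC")) {
  stopifnot(inherits(d, "peptide_dataset"), nrow(d) >= 1L)
  reg <- encoder_registry()
  if (is.character(encoders)) {
    specs <- stats::setNames(vector("list", length(encoders)), encoders)
  } else if (is.list(encoders) && !is.null(names(encoders))) {
    specs <- encoders
  } else {
    stop("`encoders` must be a character vector or a named list of parameter overrides")
  }
  if (length(specs) == 0L) stop("empty encoder specification")
  unknown <- setdiff(names(specs), names(reg))
  if (length(unknown)) stop("unknown encoder(s): ", paste(unknown, collapse = ", "))

  lens <- nchar(d$residues)
  blocks <- lapply(names(specs), function(nm) {
    params <- utils::modifyList(reg[[nm]]$params, specs[[nm]] %||% list())
    minL <- encoder_min_length(nm, params)
    short <- d$id[lens < minL]
    if (length(short)) {
      stop("sequence(s) too short for ", nm, " (needs length >= ", minL, "): ",
           paste(short, collapse = ", "))
    }
    rows <- lapply(d$residues, function(s) do.call(reg[[nm]]$fn, c(list(s), params)))
    do.call(rbind, rows)
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- d$id
  attr(m, "encoder_spec") <- lapply(stats::setNames(names(specs), names(specs)),
    function(nm) utils::modifyList(reg[[nm]]$params, specs[[nm]] %||% list()))
  m
}
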