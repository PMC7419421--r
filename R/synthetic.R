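#' Define a class-specific copy-number signature
#'
#' A signature is a set of non-overlapping gene segments that a tumor class
#' gains or loses. Each segment is applied all-or-none per sample with a
#' given penetrance, mimicking the segmental nature of real CNA: recurrent
#' arm- or focal-level events shared by a tumor type, present in most but
#' not all samples of the type.
#'
#' @param class_name class (tissue-of-origin) name.
#' @param segments data.frame with columns `start` (1-based first gene
#'   index), `length` (>= 1), `alteration` (integer in -2,-1,1,2) and
#'   `penetrance` (in (0,1]).
#' @return object of class `class_signature`.
#' @export
class_signature <- function(class_name, segments) {
  segments <- as.data.frame(segments)
  needed <- c("start", "length", "alteration", "penetrance")
  if (!all(needed %in% colnames(segments)))
    stop("segments needs columns: ", paste(needed, collapse = ", "))
  if (nrow(segments) == 0) stop("signature needs at least one segment")
  if (any(segments$length < 1)) stop("segment length must be >= 1")
  if (!all(segments$alteration %in% c(-2L, -1L, 1L, 2L)))
    stop("alteration must be in {-2,-1,1,2}")
  if (any(segments$penetrance <= 0 | segments$penetrance > 1))
    stop("penetrance must lie in (0, 1]")
  idx <- segment_indices(segments)
  if (anyDuplicated(unlist(idx)))
    stop("segments of class '", class_name, "' overlap")
  structure(list(class_name = class_name, segments = segments),
            class = "class_signature")
}

segment_indices <- function(segments) {
  lapply(seq_len(nrow(segments)),
         function(i) seq(segments$start[i], length.out = segments$length[i]))
}

#' Specify a synthetic labeled CNA cohort
#'
#' @param n_genes number of genes on the (ordered) gene axis.
#' @param classes list of [class_signature()] objects.
#' @param n_samples_per_class samples generated per class.
#' @param background_noise_rate probability that a gene outside the
#'   sample's own class signature is randomly altered (sporadic passenger
#'   events).
#' @param noise_alteration_distribution probabilities over the alteration
#'   values -2, -1, 1, 2 for noise events; must sum to 1.
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes, classes, n_samples_per_class,
                        background_noise_rate = 0.02,
                        noise_alteration_distribution = c(`-2` = 0.15, `-1` = 0.35,
                                                          `1` = 0.35, `2` = 0.15),
                        seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_class >= 1)
  if (!length(classes) || !all(vapply(classes, inherits, TRUE, "class_signature")))
    stop("classes must be a list of class_signature objects")
  nms <- vapply(classes, `[[`, character(1), "class_name")
  if (anyDuplicated(nms)) stop("duplicate class names")
  for (cl in classes) {
    idx <- unlist(segment_indices(cl$segments))
    if (any(idx < 1 | idx > n_genes))
      stop("segments of class '", cl$class_name, "' fall outside 1..n_genes")
  }
  if (background_noise_rate < 0 || background_noise_rate > 1)
    stop("background_noise_rate must be a probability")
  p <- noise_alteration_distribution
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("noise_alteration_distribution must be 4 probabilities summing to 1")
  names(p) <- c("-2", "-1", "1", "2")
  structure(list(n_genes = as.integer(n_genes), classes = classes,
                 n_samples_per_class = as.integer(n_samples_per_class),
                 background_noise_rate = background_noise_rate,
                 noise_alteration_distribution = p, seed = as.integer(seed)),
            class = "cohort_spec")
}

noise_values <- c(-2L, -1L, 1L, 2L)

#' Generate a labeled synthetic CNA cohort
#'
#' For every sample of a class, each signature segment is switched on in
#' full (all its genes set to the segment's alteration) independently with
#' probability equal to its penetrance. Every gene outside the class's own
#' signature is then altered with probability `background_noise_rate`,
#' drawing the value from `noise_alteration_distribution`; noise never
#' overwrites signature genes, which keeps the Bayes-optimal classifier
#' tractable ([bayes_separability()]). Identical spec + seed gives a
#' bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return a labeled [cna_matrix()]; sample ids are `<class>_<i>`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  m <- length(spec$classes)
  n <- m * spec$n_samples_per_class
  vals <- matrix(0L, nrow = n, ncol = spec$n_genes)
  ids <- character(n)
  labs <- character(n)
  row <- 0L
  for (cl in spec$classes) {
    seg_idx <- segment_indices(cl$segments)
    sig_genes <- unlist(seg_idx)
    bg <- setdiff(seq_len(spec$n_genes), sig_genes)
    for (s in seq_len(spec$n_samples_per_class)) {
      row <- row + 1L
      on <- stats::runif(nrow(cl$segments)) < cl$segments$penetrance
      for (j in which(on))
        vals[row, seg_idx[[j]]] <- as.integer(cl$segments$alteration[j])
      if (spec$background_noise_rate > 0 && length(bg)) {
        hit <- bg[stats::runif(length(bg)) < spec$background_noise_rate]
        if (length(hit))
          vals[row, hit] <- sample(noise_values, length(hit), replace = TRUE,
                                   prob = spec$noise_alteration_distribution)
      }
      ids[row] <- sprintf("%s_%03d", cl$class_name, s)
      labs[row] <- cl$class_name
    }
  }
  rownames(vals) <- ids
  colnames(vals) <- sprintf("g%05d", seq_len(spec$n_genes))
  names(labs) <- ids
  cna_matrix(vals, labels = labs)
}

# Log-likelihood of one integer CNA profile under the generative model of
# one class. -Inf when the profile is impossible under that class.
class_loglik <- function(x, cl, spec) {
  ll <- 0
  seg_idx <- segment_indices(cl$segments)
  for (j in seq_len(nrow(cl$segments))) {
    xs <- x[seg_idx[[j]]]
    a <- cl$segments$alteration[j]
    p <- cl$segments$penetrance[j]
    if (all(xs == a)) ll <- ll + log(p)
    else if (all(xs == 0)) ll <- ll + log1p(-p)
    else return(-Inf)
  }
  bg <- x[-unlist(seg_idx)]
  q <- spec$background_noise_rate
  nz <- bg[bg != 0]
  n0 <- length(bg) - length(nz)
  if (length(nz)) {
    if (q == 0) return(-Inf)
    pr <- spec$noise_alteration_distribution[as.character(nz)]
    if (any(pr == 0)) return(-Inf)
    ll <- ll + length(nz) * log(q) + sum(log(pr))
  }
  if (n0 > 0) {
    if (q == 1) return(-Inf)
    ll <- ll + n0 * log1p(-q)
  }
  ll
}

#' Bayes-optimal separability of a synthetic cohort design
#'
#' Monte-Carlo estimate of the accuracy of the optimal (maximum-posterior)
#' classifier under the generative model of [generate_cohort()], with a
#' uniform class prior. This is the ceiling no trained classifier can
#' exceed in expectation, used to judge how much of the attainable signal
#' a pipeline recovers. Likelihood ties are broken uniformly at random.
#'
#' @param spec a [cohort_spec()] with at least two classes.
#' @param n_draws Monte-Carlo sample count (total across classes).
#' @param seed seed for the Monte-Carlo draw (independent of `spec$seed`).
#' @return list with `accuracy` (estimate in [1/m, 1]), `se` (binomial
#'   standard error) and `n_draws`.
#' @export
bayes_separability <- function(spec, n_draws = 3000, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- length(spec$classes)
  if (m < 2) stop("need at least two classes")
  per <- ceiling(n_draws / m)
  sim <- cohort_spec(spec$n_genes, spec$classes, per,
                     spec$background_noise_rate,
                     spec$noise_alteration_distribution, seed = seed)
  coh <- generate_cohort(sim)
  set.seed(seed + 1L)
  truth <- coh$labels
  correct <- 0L
  for (i in seq_len(nrow(coh$values))) {
    ll <- vapply(spec$classes, function(cl) class_loglik(coh$values[i, ], cl, spec),
                 numeric(1))
    best <- which(ll == max(ll))
    pick <- if (length(best) == 1) best else sample(best, 1)
    if (spec$classes[[pick]]$class_name == truth[i]) correct <- correct + 1L
  }
  n <- nrow(coh$values)
  acc <- correct / n
  list(accuracy = acc, se = sqrt(acc * (1 - acc) / n), n_draws = n)
}

#' Six-class cohort preset
#'
#' A convenience design mimicking a six-tissue pan-cancer setting (class
#' names BRCA, COADREAD, GBM, KIRC, OV, UCEC). The gene axis is split into
#' six equal blocks; each class carries three disjoint segments inside its
#' own block — a mix of deletions and amplifications whose lengths scale
#' with `n_genes` — reflecting that real tumor types are marked by several
#' recurrent arm/focal events rather than a single one. With
#' `shared_signature = TRUE` all classes carry the *same* signature, a null
#' design in which class labels are unpredictable (expected accuracy 1/6).
#'
#' @param n_genes gene count (default 1000).
#' @param n_samples_per_class default 60.
#' @param penetrance per-segment penetrance (default 0.9).
#' @param background_noise_rate sporadic alteration rate (default 0.02).
#' @param seed cohort seed.
#' @param shared_signature if TRUE, every class uses class 1's segments.
#' @return a [cohort_spec()].
#' @export
six_class_default <- function(n_genes = 1000, n_samples_per_class = 60,
                              penetrance = 0.9, background_noise_rate = 0.02,
                              seed = 1L, shared_signature = FALSE) {
  names6 <- c("BRCA", "COADREAD", "GBM", "KIRC", "OV", "UCEC")
  alts <- list(c(2, -2, 1), c(-1, 2, -2), c(2, 1, -1),
               c(-2, -1, 2), c(1, -2, 2), c(-1, 1, -2))
  block <- n_genes %/% 6
  if (block < 12) stop("n_genes too small for the six-class preset (need >= 72)")
  seg_len <- max(2L, block %/% 8)
  classes <- vector("list", 6)
  for (c0 in 1:6) {
    base <- if (shared_signature) 0L else (c0 - 1L) * block
    starts <- base + c(1L, 3L * seg_len, 5L * seg_len)
    alteration <- if (shared_signature) alts[[1]] else alts[[c0]]
    classes[[c0]] <- class_signature(
      names6[c0],
      data.frame(start = starts, length = seg_len,
                 alteration = alteration, penetrance = penetrance))
  }
  cohort_spec(n_genes, classes, n_samples_per_class,
              background_noise_rate = background_noise_rate, seed = seed)
}

#' Write or read a cohort spec as a plain-text YAML config
#'
#' @param spec a [cohort_spec()].
#' @param path output path.
#' @return `path` invisibly (write) / a [cohort_spec()] (read).
#' @export
write_cohort_spec <- function(spec, path) {
  obj <- list(
    n_genes = spec$n_genes,
    n_samples_per_class = spec$n_samples_per_class,
    background_noise_rate = spec$background_noise_rate,
    noise_alteration_distribution = as.list(spec$noise_alteration_distribution),
    seed = spec$seed,
    classes = lapply(spec$classes, function(cl)
      list(class_name = cl$class_name,
           segments = lapply(seq_len(nrow(cl$segments)), function(i)
             as.list(cl$segments[i, c("start", "length", "alteration", "penetrance")]))))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  classes <- lapply(obj$classes, function(cl)
    class_signature(cl$class_name,
                    do.call(rbind, lapply(cl$segments, as.data.frame))))
  cohort_spec(obj$n_genes, classes, obj$n_samples_per_class,
              obj$background_noise_rate,
              unlist(obj$noise_alteration_distribution), obj$seed)
}
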