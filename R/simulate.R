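## F1 outbred cross simulator: no-interference (Poisson/Haldane) meiosis
## with optional gametic transmission bias and zygotic viability selection.
## Homolog labels follow the phase convention used throughout the package:
## phase 0 means homolog 1 of that parent carries the second-listed allele
## (m, p or k) of its heterozygous genotype.

COMBO_LABELS <- c("M1P1", "M1P2", "M2P1", "M2P2")

#' Describe one simulated chromosome
#'
#' @param chromosome Chromosome label, e.g. `"chr01"`.
#' @param length_cM Genetic length L in cM (>= 0). Crossovers per meiosis
#'   are Poisson with mean `L/100`.
#' @param length_Mb Physical length in Mb; defaults to `length_cM` (1 cM/Mb).
#' @param n_markers Number of evenly spaced markers (used when
#'   `marker_cM` is not given); spans `[0, length_cM]`.
#' @param marker_cM Optional explicit marker positions in cM
#'   (non-decreasing, within `[0, length_cM]`).
#' @param marker_Mb Optional physical positions in Mb; defaults to scaling
#'   `marker_cM` linearly onto `[0, length_Mb]`.
#' @return A `chromosome_map` list.
#' @export
chromosome_map <- function(chromosome, length_cM, length_Mb = length_cM,
                           n_markers = NULL, marker_cM = NULL,
                           marker_Mb = NULL) {
  stopifnot(length_cM >= 0, length_Mb >= 0)
  if (is.null(marker_cM)) {
    if (is.null(n_markers)) stop("give n_markers or marker_cM")
    marker_cM <- if (n_markers == 1) length_cM / 2 else
      seq(0, length_cM, length.out = n_markers)
  }
  if (is.unsorted(marker_cM)) stop("marker_cM must be non-decreasing")
  if (any(marker_cM < 0 | marker_cM > length_cM))
    stop("marker_cM must lie within [0, length_cM]")
  if (is.null(marker_Mb)) {
    marker_Mb <- if (length_cM > 0) marker_cM / length_cM * length_Mb
    else seq(0, length_Mb, length.out = length(marker_cM))
  }
  if (length(marker_Mb) != length(marker_cM))
    stop("marker_Mb and marker_cM lengths differ")
  structure(list(chromosome = as.character(chromosome),
                 length_cM = length_cM, length_Mb = length_Mb,
                 marker_cM = as.numeric(marker_cM),
                 marker_Mb = as.numeric(marker_Mb)),
            class = "chromosome_map")
}

#' Gametic (prezygotic) selection specification
#'
#' Accepted gametes of the given parent carry homolog 1 at the selected
#' position with probability `t` (implemented by rejection sampling, so all
#' linkage structure with flanking markers is preserved).
#'
#' @param parent `"maternal"` or `"paternal"`.
#' @param chromosome Chromosome label.
#' @param pos_cM Position of the selected locus in cM.
#' @param t Transmission probability of homolog 1, in (0, 1).
#' @return A `selection_spec` list of kind `"gametic"`.
#' @export
sel_gametic <- function(parent = c("maternal", "paternal"), chromosome,
                        pos_cM, t) {
  parent <- match.arg(parent)
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1)
    stop("transmission probability t must lie in (0, 1)")
  structure(list(kind = "gametic", parent = parent,
                 chromosome = as.character(chromosome),
                 pos_cM = pos_cM, t = t),
            class = "selection_spec")
}

#' Zygotic (postzygotic) viability selection specification
#'
#' Zygotes survive with probability proportional to a viability weight
#' determined by which parental homologs they received. Weights can be
#' given either over the four homolog combinations (`M1P1`, `M1P2`,
#' `M2P1`, `M2P2`; maternal homolog read at `chromosome`/`pos_cM`,
#' paternal homolog at `chromosome_paternal`/`pos_paternal_cM`, which
#' default to the same locus) or over genotype codes at a marker located
#' exactly at the selected position (e.g. `c(hh = 0, hk = 1, kk = 1)`);
#' genotype weights are translated to combination weights at simulation
#' time using the marker's linkage phases.
#'
#' @param chromosome,pos_cM Locus at which the maternal homolog is read
#'   (and, by default, the paternal one).
#' @param w Named numeric weights in \[0, 1\]; at least one weight must be
#'   1 (relative viability) and not all may be 0.
#' @param chromosome_paternal,pos_paternal_cM Optional second locus for
#'   the paternal homolog, enabling two-locus (epistatic) viability
#'   selection between unlinked positions.
#' @return A `selection_spec` list of kind `"zygotic"`.
#' @export
sel_zygotic <- function(chromosome, pos_cM, w,
                        chromosome_paternal = chromosome,
                        pos_paternal_cM = pos_cM) {
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("w must be a named vector")
  if (any(w < 0 | w > 1)) stop("viability weights must lie in [0, 1]")
  by_combo <- all(names(w) %in% COMBO_LABELS)
  if (!by_combo &&
      !all(names(w) %in% c("ll", "lm", "nn", "np", "hh", "hk", "kk")))
    stop("w must be named by homolog combinations (M1P1...) or genotype codes")
  ## unspecified categories default to weight 1; validate only when the
  ## named set demonstrably covers all categories of its kind
  complete <- (by_combo && setequal(names(w), COMBO_LABELS)) ||
    setequal(names(w), c("ll", "lm")) ||
    setequal(names(w), c("nn", "np")) ||
    setequal(names(w), c("hh", "hk", "kk"))
  if (complete) {
    if (all(w == 0))
      stop("impossible selection: all viability weights are 0")
    if (max(w) != 1)
      stop("at least one viability weight must equal 1 (relative viability)")
  }
  structure(list(kind = "zygotic", chromosome = as.character(chromosome),
                 pos_cM = pos_cM,
                 chromosome_paternal = as.character(chromosome_paternal),
                 pos_paternal_cM = pos_paternal_cM,
                 w = w, by_combo = by_combo),
            class = "selection_spec")
}

#' Design of a simulated F1 outbred cross
#'
#' @param maps A `chromosome_map` or list of them.
#' @param n_progeny Number of surviving progeny to simulate (> 0).
#' @param marker_classes Segregation class per marker: a single string
#'   recycled over all markers, a vector with one entry per marker (in map
#'   order), or a named vector of proportions
#'   (e.g. `c(maternal = .39, paternal = .27, biparental = .34)`) sampled
#'   per marker using the design seed.
#' @param selections List of [sel_gametic()] / [sel_zygotic()] specs.
#' @param seed Integer seed; the whole simulation is reproducible given
#'   the design.
#' @param phase_maternal,phase_paternal Optional explicit 0/1 phase vectors
#'   (one entry per marker, in map order; entries at loci where that parent
#'   is homozygous are ignored). Default: fair random phases.
#' @return A `cross_design` list.
#' @export
cross_design <- function(maps, n_progeny, marker_classes = "paternal",
                         selections = list(), seed = NULL,
                         phase_maternal = NULL, phase_paternal = NULL) {
  if (inherits(maps, "chromosome_map")) maps <- list(maps)
  stopifnot(length(maps) > 0, all(vapply(maps, inherits, TRUE,
                                         "chromosome_map")))
  if (anyDuplicated(vapply(maps, `[[`, "", "chromosome")))
    stop("duplicate chromosome labels in maps")
  if (!is.numeric(n_progeny) || n_progeny < 1)
    stop("n_progeny must be positive")
  if (inherits(selections, "selection_spec")) selections <- list(selections)
  chroms <- vapply(maps, `[[`, "", "chromosome")
  for (s in selections) {
    refs <- if (s$kind == "zygotic")
      c(s$chromosome, s$chromosome_paternal) else s$chromosome
    if (!all(refs %in% chroms))
      stop("selection references unknown chromosome: ",
           paste(setdiff(refs, chroms), collapse = ", "))
  }
  structure(list(maps = maps, n_progeny = as.integer(n_progeny),
                 marker_classes = marker_classes, selections = selections,
                 seed = seed, phase_maternal = phase_maternal,
                 phase_paternal = phase_paternal),
            class = "cross_design")
}

#' Simulate one gamete along a chromosome
#'
#' Meiosis without interference: the number of crossovers is Poisson with
#' mean `length_cM / 100`, crossover positions are i.i.d. uniform on the
#' chromosome, and the starting homolog is a fair coin. The transmitted
#' homolog at each marker is the start homolog flipped once per crossover
#' located before the marker.
#'
#' @param map A [chromosome_map()].
#' @return A list with `indicator` (vector of 1/2 per marker) and
#'   `crossovers` (sorted cM positions).
#' @export
simulate_gamete <- function(map) {
  b <- simulate_gametes(map, 1L)
  list(indicator = b$indicator[1L, ], crossovers = b$crossovers[[1L]])
}

## vectorised batch of n gametes; returns a gamete_batch
simulate_gametes <- function(map, n) {
  stopifnot(inherits(map, "chromosome_map"), n >= 1)
  m <- length(map$marker_cM)
  start <- sample(c(1L, 2L), n, replace = TRUE)
  if (map$length_cM == 0) {
    ind <- matrix(start, nrow = n, ncol = m)
    xo <- rep(list(numeric(0)), n)
  } else {
    k <- stats::rpois(n, map$length_cM / 100)
    pos <- stats::runif(sum(k), 0, map$length_cM)
    xo <- split(pos, factor(rep.int(seq_len(n), k), levels = seq_len(n)))
    xo <- lapply(xo, sort)
    names(xo) <- NULL
    ind <- matrix(0L, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      flips <- if (k[i] == 0) integer(m) else
        findInterval(map$marker_cM, xo[[i]])
      ind[i, ] <- 1L + (start[i] - 1L + flips) %% 2L
    }
  }
  structure(list(map = map, start = start, indicator = ind,
                 crossovers = xo), class = "gamete_batch")
}

## transmitted homolog (1/2) at an arbitrary cM position for each gamete
homolog_at <- function(batch, pos_cM) {
  flips <- vapply(batch$crossovers, function(x) sum(x <= pos_cM), 0L)
  1L + (batch$start - 1L + flips) %% 2L
}

#' Apply gametic selection to a batch of gametes
#'
#' Rejection sampling: gametes carrying homolog 1 at the selected position
#' are kept with probability `t / max(t, 1 - t)`, homolog-2 carriers with
#' `(1 - t) / max(t, 1 - t)`, so accepted gametes carry homolog 1 with
#' probability `t` while all linkage structure is untouched.
#'
#' @param batch A gamete batch from the simulator.
#' @param spec A [sel_gametic()] spec (its chromosome must match the batch).
#' @return The filtered gamete batch (possibly with fewer gametes).
#' @export
apply_gametic_selection <- function(batch, spec) {
  stopifnot(inherits(batch, "gamete_batch"),
            inherits(spec, "selection_spec"))
  if (spec$kind != "gametic") stop("spec must be a gametic selection")
  if (spec$chromosome != batch$map$chromosome)
    stop("spec chromosome does not match batch chromosome")
  hom <- homolog_at(batch, spec$pos_cM)
  p_keep <- ifelse(hom == 1L, spec$t, 1 - spec$t) / max(spec$t, 1 - spec$t)
  keep <- stats::runif(length(hom)) < p_keep
  subset_batch(batch, keep)
}

subset_batch <- function(batch, keep) {
  structure(list(map = batch$map, start = batch$start[keep],
                 indicator = batch$indicator[keep, , drop = FALSE],
                 crossovers = batch$crossovers[keep]),
            class = "gamete_batch")
}

## translate genotype-code viability weights to the four homolog combos
## using the phases of the marker at the selected position
zygotic_combo_weights <- function(spec, loci) {
  if (spec$by_combo) {
    w4 <- stats::setNames(rep(1, 4), COMBO_LABELS)
    w4[names(spec$w)] <- spec$w
    if (all(w4 == 0))
      stop("impossible selection: all viability weights are 0")
    return(w4)
  }
  if (!identical(spec$chromosome, spec$chromosome_paternal) ||
      spec$pos_cM != spec$pos_paternal_cM)
    stop("genotype-code viability weights require a single locus")
  at <- which(loci$chromosome == spec$chromosome &
                abs(loci$genetic_pos - spec$pos_cM) < 1e-8)
  if (!length(at))
    stop("no marker at the zygotic selection position ", spec$chromosome,
         ":", spec$pos_cM, "; genotype-code weights need one")
  at <- at[1]
  seg <- loci$seg_class[at]
  qm <- loci$phase_maternal[at]
  qp <- loci$phase_paternal[at]
  code_of <- function(hm, hp) {
    switch(seg,
           maternal = if ((hm == 1) == (qm == 0)) "lm" else "ll",
           paternal = if ((hp == 1) == (qp == 0)) "np" else "nn",
           biparental = {
             k <- ((hm == 1) == (qm == 0)) + ((hp == 1) == (qp == 0))
             c("hh", "hk", "kk")[k + 1]
           })
  }
  w4 <- vapply(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), function(h) {
    code <- code_of(h[1], h[2])
    if (code %in% names(spec$w)) spec$w[[code]] else 1
  }, 0)
  stats::setNames(w4, COMBO_LABELS)
}

#' Simulate a full F1 outbred population with known truth
#'
#' Simulates `n_progeny` surviving individuals from a [cross_design()]:
#' independent meioses per parent and chromosome, gametic selection by
#' rejection on the gamete stream, zygotic selection by rejection on the
#' united zygote (before genotyping), then genotype codes derived from the
#' transmitted homologs, marker classes and linkage phases.
#'
#' @param design A [cross_design()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (per parent: per-chromosome transmitted-homolog indicator matrices
#'   (progeny x markers, values 1/2) and per-progeny crossover positions).
#' @export
simulate_population <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  if (!is.null(design$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(design$seed)
  }

  maps <- design$maps
  chroms <- vapply(maps, `[[`, "", "chromosome")
  m_per_chr <- vapply(maps, function(x) length(x$marker_cM), 0L)
  m_total <- sum(m_per_chr)

  classes <- resolve_marker_classes(design$marker_classes, m_total)
  qm <- design$phase_maternal %||% sample(0:1, m_total, replace = TRUE)
  qp <- design$phase_paternal %||% sample(0:1, m_total, replace = TRUE)
  stopifnot(length(qm) == m_total, length(qp) == m_total)

  loci <- do.call(rbind, lapply(seq_along(maps), function(i) {
    data.frame(marker_id = sprintf("%s_m%04d", chroms[i],
                                   seq_len(m_per_chr[i])),
               chromosome = chroms[i],
               genetic_pos = maps[[i]]$marker_cM,
               physical_pos = maps[[i]]$marker_Mb,
               stringsAsFactors = FALSE)
  }))
  loci$seg_class <- classes
  loci$phase_maternal <- ifelse(classes %in% c("maternal", "biparental"),
                                as.integer(qm), NA_integer_)
  loci$phase_paternal <- ifelse(classes %in% c("paternal", "biparental"),
                                as.integer(qp), NA_integer_)

  gam_sel <- Filter(function(s) s$kind == "gametic", design$selections)
  zyg_sel <- Filter(function(s) s$kind == "zygotic", design$selections)
  zyg_w <- lapply(zyg_sel, zygotic_combo_weights, loci = loci)

  n <- design$n_progeny
  acc <- list(maternal = vector("list", length(maps)),
              paternal = vector("list", length(maps)))  # accepted per chr
  got <- 0L
  guard <- 0L
  while (got < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("selection acceptance rate too low; giving up")
    need <- n - got
    b <- max(32L, ceiling(need * 1.5))
    cand <- list(maternal = vector("list", length(maps)),
                 paternal = vector("list", length(maps)))
    for (parent in c("maternal", "paternal")) {
      for (i in seq_along(maps)) {
        g <- simulate_gametes(maps[[i]], b)
        for (s in gam_sel)
          if (s$parent == parent && s$chromosome == chroms[i]) {
            hom <- homolog_at(g, s$pos_cM)
            p_keep <- ifelse(hom == 1L, s$t, 1 - s$t) / max(s$t, 1 - s$t)
            ## thin the stream but keep batches aligned across chromosomes:
            ## rejection is applied jointly below via acceptance weights
            attr(g, "p_keep") <- (attr(g, "p_keep") %||% rep(1, b)) * p_keep
          }
        cand[[parent]][[i]] <- g
      }
    }
    ## per-candidate acceptance probability: gametic streams x zygote weights
    p_acc <- rep(1, b)
    for (parent in c("maternal", "paternal"))
      for (i in seq_along(maps)) {
        pk <- attr(cand[[parent]][[i]], "p_keep")
        if (!is.null(pk)) p_acc <- p_acc * pk
      }
    for (k in seq_along(zyg_sel)) {
      s <- zyg_sel[[k]]
      hm <- homolog_at(cand$maternal[[match(s$chromosome, chroms)]],
                       s$pos_cM)
      hp <- homolog_at(cand$paternal[[match(s$chromosome_paternal, chroms)]],
                       s$pos_paternal_cM)
      combo <- COMBO_LABELS[(hm - 1L) * 2L + hp]
      p_acc <- p_acc * zyg_w[[k]][combo]
    }
    keep <- which(stats::runif(b) < p_acc)
    if (length(keep) > need) keep <- keep[seq_len(need)]
    for (parent in c("maternal", "paternal"))
      for (i in seq_along(maps)) {
        kept <- subset_batch(cand[[parent]][[i]], keep)
        acc[[parent]][[i]] <- if (is.null(acc[[parent]][[i]])) kept else
          merge_batches(acc[[parent]][[i]], kept)
      }
    got <- got + length(keep)
  }

  progeny_ids <- sprintf("ind%04d", seq_len(n))
  codes <- matrix(MISSING_CODE, nrow = n, ncol = m_total,
                  dimnames = list(progeny_ids, loci$marker_id))
  off <- 0L
  for (i in seq_along(maps)) {
    cols <- off + seq_len(m_per_chr[i])
    im <- acc$maternal[[i]]$indicator
    ip <- acc$paternal[[i]]$indicator
    cl <- classes[cols]
    qmi <- matrix(qm[cols], nrow = n, ncol = m_per_chr[i], byrow = TRUE)
    qpi <- matrix(qp[cols], nrow = n, ncol = m_per_chr[i], byrow = TRUE)
    sec_m <- (im == 1L) == (qmi == 0L)  # mother passed second allele (m/k)
    sec_p <- (ip == 1L) == (qpi == 0L)  # father passed second allele (p/k)
    for (j in seq_along(cols)) {
      codes[, cols[j]] <- switch(cl[j],
        maternal   = ifelse(sec_m[, j], "lm", "ll"),
        paternal   = ifelse(sec_p[, j], "np", "nn"),
        biparental = c("hh", "hk", "kk")[sec_m[, j] + sec_p[, j] + 1L])
    }
    off <- off + m_per_chr[i]
  }

  truth <- list(
    maternal = stats::setNames(lapply(acc$maternal, truth_entry,
                                      progeny_ids = progeny_ids), chroms),
    paternal = stats::setNames(lapply(acc$paternal, truth_entry,
                                      progeny_ids = progeny_ids), chroms))

  list(genotypes = genotype_matrix(loci, codes, progeny_ids),
       truth = truth, design = design)
}

merge_batches <- function(a, b) {
  structure(list(map = a$map, start = c(a$start, b$start),
                 indicator = rbind(a$indicator, b$indicator),
                 crossovers = c(a$crossovers, b$crossovers)),
            class = "gamete_batch")
}

truth_entry <- function(batch, progeny_ids) {
  ind <- batch$indicator
  rownames(ind) <- progeny_ids
  list(indicator = ind,
       crossovers = stats::setNames(batch$crossovers, progeny_ids),
       marker_cM = batch$map$marker_cM)
}

resolve_marker_classes <- function(spec, m_total) {
  if (is.character(spec) && length(spec) == 1 && is.null(names(spec))) {
    if (!spec %in% SEG_CLASSES) stop("unknown marker class: ", spec)
    return(rep(spec, m_total))
  }
  if (!is.null(names(spec))) {  # proportions
    if (!all(names(spec) %in% SEG_CLASSES))
      stop("marker class proportions must be named by seg classes")
    p <- spec / sum(spec)
    return(sample(names(p), m_total, replace = TRUE, prob = p))
  }
  if (length(spec) != m_total)
    stop("marker_classes must have one entry per marker (", m_total, ")")
  if (!all(spec %in% SEG_CLASSES)) stop("unknown marker class present")
  as.character(spec)
}
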