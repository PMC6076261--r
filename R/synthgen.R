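# Seeded synthetic-data generators with full ground truth. These stand in
# for the wet-lab inputs of the quantification pipeline: high-content
# fields (nuclear / viability / GFP channels), tandem-reporter fields
# (red / green / nuclear), and assay tables drawn from the closed-form
# models in models.R.

# run code under a temporary RNG seed without disturbing the caller's stream
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  code
}

# order-stable sub-seed stream derived from one global seed
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1117) %% 2147483629)
}

#' Field generator specification
#'
#' All geometric and photometric parameters of the simulated adherent-cell
#' field. Defaults emulate a 20x high-content acquisition: disc-like nuclei
#' inside disc-like cells, diffuse cytoplasmic reporter, small bright
#' puncta, a linear background gradient, Poisson shot noise plus additive
#' Gaussian read noise.
#'
#' @slot width,height field size in pixels.
#' @slot nCells number of cells to place.
#' @slot cellRadius,nucleusRadius disc radii in pixels
#'   (`nucleusRadius < cellRadius`).
#' @slot deadFraction expected fraction of dead cells (Bernoulli per cell).
#' @slot punctaDist list describing the per-cell punctum-count
#'   distribution: `list(name = "poisson", mean = 4)` or
#'   `list(name = "fixed", count = k)`.
#' @slot punctumRadius punctum disc radius, pixels.
#' @slot punctumPeak punctum peak intensity above cytoplasm (a.u.).
#' @slot background background level (a.u.).
#' @slot backgroundGradient linear intensity ramp per pixel (columns).
#' @slot noiseGaussianSD additive Gaussian noise SD (a.u.).
#' @slot noisePoisson apply Poisson shot noise before the Gaussian term.
#' @slot minSeparation minimum pairwise distance between cell centers, px.
#' @slot deadOverlapFraction fraction of a dead cell's disc covered by
#'   viability stain (default 0.8, far from the 0.5 decision rule);
#'   `ambiguous = TRUE` instead draws it near 0.5 for threshold testing.
#' @slot ambiguous logical, see `deadOverlapFraction`.
#' @slot cytoplasmLevel diffuse reporter intensity over the cell disc.
#' @slot nuclearPeak,viabilityPeak stain intensities (a.u.).
#' @slot edgeSigma Gaussian blur applied to the noiseless structure image
#'   (soft disc edges).
#' @slot brightnessSdLog sdlog of the per-cell lognormal brightness factor.
#' @slot seed integer RNG seed.
#' @export
setClass("FieldSpec",
  representation(width = "integer", height = "integer", nCells = "integer",
    cellRadius = "numeric", nucleusRadius = "numeric",
    deadFraction = "numeric", punctaDist = "list", punctumRadius = "numeric",
    punctumPeak = "numeric", background = "numeric",
    backgroundGradient = "numeric", noiseGaussianSD = "numeric",
    noisePoisson = "logical", minSeparation = "numeric",
    deadOverlapFraction = "numeric", ambiguous = "logical",
    cytoplasmLevel = "numeric", nuclearPeak = "numeric",
    viabilityPeak = "numeric", edgeSigma = "numeric",
    brightnessSdLog = "numeric", seed = "integer")
)

setValidity("FieldSpec", function(object) {
  if (object@width < 1 || object@height < 1)
    return("field dimensions must be positive")
  if (object@nCells < 0) return("nCells must be >= 0")
  if (object@nucleusRadius <= 0 || object@cellRadius <= 0 ||
      object@punctumRadius <= 0)
    return("all radii must be > 0")
  if (object@nucleusRadius >= object@cellRadius)
    return("nucleusRadius must be < cellRadius")
  if (object@deadFraction < 0 || object@deadFraction > 1)
    return("deadFraction must be in [0, 1]")
  if (!object@punctaDist$name %in% c("poisson", "fixed"))
    return("punctaDist$name must be 'poisson' or 'fixed'")
  if (object@noiseGaussianSD < 0) return("noiseGaussianSD must be >= 0")
  if (object@deadOverlapFraction <= 0 || object@deadOverlapFraction > 1)
    return("deadOverlapFraction must be in (0, 1]")
  TRUE
})

#' Construct a FieldSpec
#'
#' @param width,height,nCells,cellRadius,nucleusRadius,deadFraction
#'   see [FieldSpec-class].
#' @param punctaDist,punctumRadius,punctumPeak,background,backgroundGradient
#'   see [FieldSpec-class].
#' @param noiseGaussianSD,noisePoisson,minSeparation,deadOverlapFraction
#'   see [FieldSpec-class].
#' @param ambiguous,cytoplasmLevel,nuclearPeak,viabilityPeak,edgeSigma
#'   see [FieldSpec-class].
#' @param brightnessSdLog,seed see [FieldSpec-class].
#' @return a validated [FieldSpec-class].
#' @export
fieldSpec <- function(width = 400L, height = 400L, nCells = 50L,
                      cellRadius = 14, nucleusRadius = 5,
                      deadFraction = 0.2,
                      punctaDist = list(name = "poisson", mean = 4),
                      punctumRadius = 2, punctumPeak = 120,
                      background = 100, backgroundGradient = 0.05,
                      noiseGaussianSD = 5, noisePoisson = TRUE,
                      minSeparation = 30, deadOverlapFraction = 0.8,
                      ambiguous = FALSE, cytoplasmLevel = 40,
                      nuclearPeak = 150, viabilityPeak = 130,
                      edgeSigma = 0.8, brightnessSdLog = 0.2, seed = 1L) {
  new("FieldSpec", width = as.integer(width), height = as.integer(height),
      nCells = as.integer(nCells), cellRadius = cellRadius,
      nucleusRadius = nucleusRadius, deadFraction = deadFraction,
      punctaDist = punctaDist, punctumRadius = punctumRadius,
      punctumPeak = punctumPeak, background = background,
      backgroundGradient = backgroundGradient,
      noiseGaussianSD = noiseGaussianSD, noisePoisson = noisePoisson,
      minSeparation = minSeparation,
      deadOverlapFraction = deadOverlapFraction, ambiguous = ambiguous,
      cytoplasmLevel = cytoplasmLevel, nuclearPeak = nuclearPeak,
      viabilityPeak = viabilityPeak, edgeSigma = edgeSigma,
      brightnessSdLog = brightnessSdLog, seed = as.integer(seed))
}

# rejection-sample nCells centers pairwise >= minSep apart within margins
placeCenters <- function(spec) {
  n <- spec@nCells
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  m <- ceiling(spec@cellRadius)
  if (spec@height - 2 * m < 1 || spec@width - 2 * m < 1)
    stop("invalid spec: field smaller than one cell")
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; tries <- 0L; maxTries <- 300L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries) stop("field overcrowded: could not place ",
                               n, " cells at separation ", spec@minSeparation)
    r <- stats::runif(1, m + 1, spec@height - m)
    cc <- stats::runif(1, m + 1, spec@width - m)
    if (placed == 0L ||
        all((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - cc)^2 >=
            spec@minSeparation^2)) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- cc
    }
  }
  cbind(row = rows, col = cols)
}

# add `value` over a disc; modifies and returns the image
paintDisc <- function(img, r0, c0, radius, value) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  ci <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  sub <- outer((ri - r0)^2, (ci - c0)^2, "+") <= radius^2
  img[ri, ci] <- img[ri, ci] + value * sub
  img
}

# place k punctum centers inside a disc, pairwise >= sep apart; the whole
# configuration is restarted on a dead end, and only if every restart
# fails is the separation constraint dropped for the remaining points, so
# the ground-truth count always equals the sampled count
placePuncta <- function(r0, c0, maxR, k, sep) {
  if (k == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  onePoint <- function() {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- maxR * sqrt(stats::runif(1))
    c(r0 + rad * sin(ang), c0 + rad * cos(ang))
  }
  for (restart in 1:50) {
    rows <- numeric(k); cols <- numeric(k)
    done <- TRUE
    for (i in seq_len(k)) {
      placed <- FALSE
      for (try in 1:60) {
        p <- onePoint()
        if (i == 1L ||
            all((rows[seq_len(i - 1)] - p[1])^2 +
                (cols[seq_len(i - 1)] - p[2])^2 >= sep^2)) {
          rows[i] <- p[1]; cols[i] <- p[2]; placed <- TRUE; break
        }
      }
      if (!placed) { done <- FALSE; break }
    }
    if (done) return(cbind(row = rows, col = cols))
  }
  for (i in seq_len(k)) {  # overfull cell: accept crowding
    if (rows[i] == 0 && cols[i] == 0) {
      p <- onePoint(); rows[i] <- p[1]; cols[i] <- p[2]
    }
  }
  cbind(row = rows, col = cols)
}

samplePunctaCounts <- function(dist, n) {
  if (n == 0L) return(integer(0))
  switch(dist$name,
    poisson = stats::rpois(n, dist$mean),
    fixed   = rep(as.integer(dist$count), n),
    stop("unknown puncta distribution: ", dist$name))
}

applyNoise <- function(img, spec) {
  if (spec@noisePoisson)
    img <- matrix(as.numeric(stats::rpois(length(img), lambda = pmax(img, 0))),
                  nrow(img), ncol(img))
  if (spec@noiseGaussianSD > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = spec@noiseGaussianSD),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

backgroundPlane <- function(spec) {
  matrix(spec@background, spec@height, spec@width) +
    matrix(rep((seq_len(spec@width) - 1) * spec@backgroundGradient,
               each = spec@height), spec@height, spec@width)
}

# shared scene construction for both field generators
buildScene <- function(spec, tandem, redOnlyFraction) {
  centers <- placeCenters(spec)
  n <- nrow(centers)
  dead <- if (n) stats::runif(n) < spec@deadFraction else logical(0)
  bright <- if (n) stats::rlnorm(n, 0, spec@brightnessSdLog) else numeric(0)
  overlap <- ifelse(dead,
    if (spec@ambiguous) stats::runif(n, 0.45, 0.55) else
      spec@deadOverlapFraction, 0)
  counts <- samplePunctaCounts(spec@punctaDist, n)
  maxR <- max(spec@cellRadius - spec@punctumRadius - 1, 1)
  # center separation 2r + 3: puncta stay optically resolvable after the
  # soft-edge blur, emulating distinct vesicles
  sep <- 2 * spec@punctumRadius + 3
  pl <- vector("list", n)
  for (i in seq_len(n)) {
    p <- placePuncta(centers[i, 1], centers[i, 2], maxR, counts[i], sep)
    if (counts[i] > 0L)
      pl[[i]] <- data.frame(row = p[, 1], col = p[, 2],
                            radius = spec@punctumRadius, cell = i)
  }
  puncta <- if (length(pl)) do.call(rbind, pl) else NULL
  if (is.null(puncta))
    puncta <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0), cell = integer(0))
  puncta$class <- if (tandem && nrow(puncta)) {
    ifelse(stats::runif(nrow(puncta)) < redOnlyFraction, "red_only", "yellow")
  } else rep("green", nrow(puncta))
  cells <- data.frame(row = centers[, 1], col = centers[, 2],
                      nucleusRadius = rep(spec@nucleusRadius, n),
                      cellRadius = rep(spec@cellRadius, n),
                      dead = dead, viabilityOverlap = overlap,
                      brightness = bright)
  list(cells = cells, puncta = puncta)
}

renderChannels <- function(spec, scene, tandem) {
  cells <- scene$cells; puncta <- scene$puncta
  bg <- backgroundPlane(spec)
  nuc <- matrix(0, spec@height, spec@width)
  cyto <- nuc; via <- nuc
  for (i in seq_len(nrow(cells))) {
    b <- cells$brightness[i]
    nuc <- paintDisc(nuc, cells$row[i], cells$col[i], spec@nucleusRadius,
                     spec@nuclearPeak * b)
    cyto <- paintDisc(cyto, cells$row[i], cells$col[i], spec@cellRadius,
                      spec@cytoplasmLevel * b)
    if (cells$dead[i])
      via <- paintDisc(via, cells$row[i], cells$col[i],
                       spec@cellRadius * sqrt(cells$viabilityOverlap[i]),
                       spec@viabilityPeak)
  }
  punctaLayer <- function(rows) {
    p <- matrix(0, spec@height, spec@width)
    for (k in rows)
      p <- paintDisc(p, puncta$row[k], puncta$col[k], puncta$radius[k],
                     spec@punctumPeak * cells$brightness[puncta$cell[k]])
    p
  }
  blur <- function(m) gaussianBlur(m, spec@edgeSigma)
  if (!tandem) {
    list(nuclear = bg + blur(nuc),
         viability = bg + blur(via),
         gfp = bg + blur(cyto + punctaLayer(seq_len(nrow(puncta)))))
  } else {
    yellow <- which(puncta$class == "yellow")
    list(nuclear = bg + blur(nuc),
         red = bg + blur(cyto + punctaLayer(seq_len(nrow(puncta)))),
         green = bg + blur(cyto + punctaLayer(yellow)))
  }
}

#' Generate a high-content screening field with ground truth
#'
#' Simulates one three-channel field (nuclear stain, viability stain,
#' GFP-LC3) as parameterized by the [FieldSpec-class] argument: cells are
#' soft-edged discs at
#' pairwise-separated random centers; dead cells carry a viability-stain
#' disc covering `deadOverlapFraction` of their cell disc; puncta are
#' placed strictly inside their owning cell's disc. Identical spec and
#' seed give bit-identical output.
#'
#' @param spec a [FieldSpec-class] (see [fieldSpec()]).
#' @return list with elements `field` ([LabeledField-class]) and `truth`
#'   ([FieldTruth-class]).
#' @examples
#' sim <- genHcsField(fieldSpec(nCells = 5L, width = 150L, height = 150L))
#' sim$field
#' sim$truth
#' @export
genHcsField <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    scene <- buildScene(spec, tandem = FALSE, redOnlyFraction = 0)
    ch <- renderChannels(spec, scene, tandem = FALSE)
    ch <- lapply(ch, applyNoise, spec = spec)
    list(field = LabeledField(ch, provenance = paste0("synthetic hcs seed=",
                                                      spec@seed)),
         truth = new("FieldTruth", cells = scene$cells,
                     puncta = scene$puncta, seed = spec@seed))
  })
}

#' Generate a tandem-reporter (red/green) field with ground truth
#'
#' Simulates the tandem mRFP-eGFP-LC3 readout: every punctum appears in the
#' red channel; a punctum is `yellow` (signal co-located in the green
#' channel, an autophagosome) or `red_only` (an autolysosome, GFP quenched)
#' by a seeded Bernoulli draw with `P(red_only) = redOnlyFraction`.
#'
#' @param spec a [FieldSpec-class].
#' @param redOnlyFraction probability that a punctum is red-only, in
#'   `[0, 1]`.
#' @return list with `field` (channels `red`, `green`, `nuclear`) and
#'   `truth` (punctum `class` column records the ground truth).
#' @export
genTandemField <- function(spec, redOnlyFraction) {
  validObject(spec)
  if (redOnlyFraction < 0 || redOnlyFraction > 1)
    stop("redOnlyFraction must be in [0, 1]")
  withSeed(spec@seed, {
    scene <- buildScene(spec, tandem = TRUE,
                        redOnlyFraction = redOnlyFraction)
    ch <- renderChannels(spec, scene, tandem = TRUE)
    ch <- lapply(ch, applyNoise, spec = spec)
    list(field = LabeledField(ch, provenance = paste0(
           "synthetic tandem seed=", spec@seed)),
         truth = new("FieldTruth", cells = scene$cells,
                     puncta = scene$puncta, seed = spec@seed))
  })
}

#' Assay-table generator specification
#'
#' @param model one of `"fourPL"`, `"michaelis_menten_uncompetitive"`,
#'   `"michaelis_menten_competitive"`, `"michaelis_menten_noncompetitive"`,
#'   `"binding_1to1"`, `"one_compartment_oral"`, `"progress_linear"`.
#' @param params named list of true model parameters (see Details).
#' @param design named list of design points: `conc` (uM) for dose-response
#'   and binding, `S` and `I` (uM) for kinetics, `times` (h) for PK,
#'   `times` (s) for progress curves.
#' @param n replicate count (>= 1).
#' @param noiseCV relative (lognormal-free, Gaussian) noise coefficient of
#'   variation; 0 for noiseless replicates.
#' @param noiseSD additive noise SD (applied after `noiseCV`).
#' @param seed integer seed.
#'
#' @details Required parameters by model: 4PL `top, bottom, ic50, h`
#' (uM for `ic50`); kinetics `Vmax` (M/s), `KM`, `Ki` (uM); binding
#' `KD, P0` (uM), `Ffree, dF` (signal units); oral PK
#' `dose` (mg/kg), `ka, ke` (1/h), `VF` (L/kg), optional `mw` (g/mol);
#' progress `slope` (RFU/s), `intercept` (RFU).
#' @return a list of class spec used by [genAssayTable()].
#' @export
assaySpec <- function(model, params, design, n = 3L, noiseCV = 0,
                      noiseSD = 0, seed = 1L) {
  models <- c("fourPL", "michaelis_menten_uncompetitive",
              "michaelis_menten_competitive",
              "michaelis_menten_noncompetitive", "binding_1to1",
              "one_compartment_oral", "progress_linear")
  if (!model %in% models)
    stop("unknown model '", model, "'")
  req <- switch(model,
    fourPL = c("top", "bottom", "ic50", "h"),
    michaelis_menten_uncompetitive = ,
    michaelis_menten_competitive = ,
    michaelis_menten_noncompetitive = c("Vmax", "KM", "Ki"),
    binding_1to1 = c("KD", "P0", "Ffree", "dF"),
    one_compartment_oral = c("dose", "ka", "ke", "VF"),
    progress_linear = c("slope", "intercept"))
  missing <- setdiff(req, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", model, ": ",
         paste(missing, collapse = ", "))
  if (n < 1) stop("n must be >= 1")
  if (noiseCV < 0 || noiseSD < 0) stop("noise must be >= 0")
  dp <- unlist(design)
  if (!length(dp) || any(!is.finite(dp)))
    stop("design points must be finite")
  structure(list(model = model, params = params, design = design,
                 n = as.integer(n), noiseCV = noiseCV, noiseSD = noiseSD,
                 seed = as.integer(seed)), class = "AssaySpecList")
}

#' Default enzyme-kinetic plate design
#'
#' Substrate series spanning 10 to 124.4 uM (2-fold steps up to the assay
#' ceiling) and inhibitor series 0 plus 6 to 54 uM (3-fold steps), i.e. the
#' substrate-by-inhibitor grid used for inhibition-mode work.
#'
#' @return list with numeric vectors `S` and `I` (uM).
#' @export
defaultKineticGrid <- function() {
  list(S = c(10, 20, 40, 80, 124.4), I = c(0, 6, 18, 54))
}

evalAssayModel <- function(model, params, df) {
  with(params, switch(model,
    fourPL = fourPL(df$conc_uM, top, bottom, ic50, h),
    michaelis_menten_uncompetitive =
      michaelisMentenRate(df$substrate_uM, Vmax, KM, df$inhibitor_uM, Ki,
                          "uncompetitive"),
    michaelis_menten_competitive =
      michaelisMentenRate(df$substrate_uM, Vmax, KM, df$inhibitor_uM, Ki,
                          "competitive"),
    michaelis_menten_noncompetitive =
      michaelisMentenRate(df$substrate_uM, Vmax, KM, df$inhibitor_uM, Ki,
                          "noncompetitive"),
    binding_1to1 = Ffree + dF * fractionBound(df$conc_uM, P0, KD),
    one_compartment_oral = pkOralConcentration(df$time_h, dose, ka, ke, VF,
      mw = if (is.null(params$mw)) 425 else params$mw),
    progress_linear = intercept + slope * df$time_s))
}

#' Generate a simulated assay table
#'
#' Emits the noiseless model values (`is_truth = TRUE`, `replicate = 0`)
#' plus `n` noisy replicates per design point, drawn from the model named
#' by `spec$model`. With zero noise the replicates equal the closed-form model
#' values exactly.
#'
#' @param spec an [assaySpec()].
#' @return a [SimulatedAssay-class]; value columns follow the model
#'   (`response`, `rate_M_per_s`, `conc_plasma_uM`, or `rfu`).
#' @examples
#' sp <- assaySpec("fourPL",
#'   params = list(top = 1, bottom = 0, ic50 = 25, h = 1),
#'   design = list(conc = c(1, 5, 25, 125, 625)), n = 3, noiseCV = 0.05)
#' genAssayTable(sp)
#' @export
genAssayTable <- function(spec) {
  stopifnot(inherits(spec, "AssaySpecList"))
  base <- switch(spec$model,
    fourPL = ,
    binding_1to1 = data.frame(conc_uM = spec$design$conc),
    one_compartment_oral = data.frame(time_h = spec$design$times),
    progress_linear = data.frame(time_s = spec$design$times),
    expand.grid(substrate_uM = spec$design$S, inhibitor_uM = spec$design$I))
  valueCol <- switch(spec$model,
    fourPL = , binding_1to1 = "response",
    one_compartment_oral = "conc_plasma_uM",
    progress_linear = "rfu",
    "rate_M_per_s")
  truthVals <- evalAssayModel(spec$model, spec$params, base)
  rows <- withSeed(spec$seed, {
    out <- vector("list", spec$n + 1L)
    truth <- base
    truth[[valueCol]] <- truthVals
    truth$replicate <- 0L; truth$is_truth <- TRUE
    out[[1]] <- truth
    for (r in seq_len(spec$n)) {
      rep <- base
      v <- truthVals
      if (spec$noiseCV > 0)
        v <- v * (1 + stats::rnorm(length(v), sd = spec$noiseCV))
      if (spec$noiseSD > 0)
        v <- v + stats::rnorm(length(v), sd = spec$noiseSD)
      rep[[valueCol]] <- v
      rep$replicate <- r; rep$is_truth <- FALSE
      out[[r + 1L]] <- rep
    }
    do.call(rbind, out)
  })
  new("SimulatedAssay", model = spec$model, data = rows,
      truth = spec$params, seed = spec$seed)
}
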