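# Synthetic paired image + omics fixture generator.
#
# Emulates the statistical structure the conditional diffusion model
# assumes: a low-rank multi-omic tensor whose per-patient latent factors
# deterministically control the content of a paired grayscale image (an
# elliptical "phantom" blob on a dark background), plus Gaussian noise on
# both sides. A decoder recovers the controlled image attributes so
# conditional generation can be measured instrument-style.

#' Specification of a synthetic paired fixture set
#'
#' Factor semantics (the effect map): factor 1 shifts the blob center
#' horizontally, factor 2 vertically, factor 3 scales the radius, factor 4
#' the peak intensity; remaining factors are inert distractors. Effects are
#' smooth, strictly monotone tanh maps sized so that two standard deviations
#' of a factor move the attribute across >= 30% of the image width.
#'
#' @param n_patients number of paired samples.
#' @param size image side length (power-of-two compatible with the
#'   denoiser depth).
#' @param R number of latent factors (>= 4).
#' @param noise_sd pixel Gaussian noise sd (unit-scale images).
#' @param omics_noise_sd Gaussian noise sd on the omics matrices.
#' @param n_genes genes per modality.
#' @param seed root seed; factors, loadings and noise use derived
#'   sub-streams.
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_patients = 128, size = 16, R = 8,
                         noise_sd = 0.02, omics_noise_sd = 0.1,
                         n_genes = 60, seed = 7) {
  if (R < 4) stop("need R >= 4 factors (4 controlled image attributes)",
                  call. = FALSE)
  structure(list(n_patients = n_patients, size = size, R = R,
                 noise_sd = noise_sd, omics_noise_sd = omics_noise_sd,
                 n_genes = n_genes, seed = seed),
            class = "fixture_spec")
}

#' Draw latent patient factors
#'
#' Factor scores are i.i.d. standard normal, deterministic given the
#' fixture seed.
#'
#' @param spec a [fixture_spec()].
#' @return `n_patients x R` matrix with patient/factor dimnames.
#' @export
make_factors <- function(spec) {
  set.seed(derive_seed(spec$seed, 11))
  f <- matrix(stats::rnorm(spec$n_patients * spec$R), spec$n_patients, spec$R)
  dimnames(f) <- list(sprintf("P%03d", seq_len(spec$n_patients)),
                      paste0("F", seq_len(spec$R)))
  f
}

# attribute map: factor scores -> blob parameters
blob_attributes <- function(tau, n) {
  list(cx = (n + 1) / 2 + 0.2 * n * tanh(tau[1] / 2),
       cy = (n + 1) / 2 + 0.2 * n * tanh(tau[2] / 2),
       r  = n * (0.15 + 0.05 * tanh(tau[3])),
       peak = 0.7 + 0.25 * tanh(tau[4]))
}

#' Render the phantom image for a condition vector
#'
#' A dark background with one bright soft-edged ellipse whose center, radius
#' and peak intensity are monotone functions of the first four factors,
#' plus seeded Gaussian pixel noise, clipped to `[0, 1]`.
#'
#' @param tau factor vector of length `spec$R`.
#' @param spec a [fixture_spec()].
#' @param noise_seed optional seed for this image's pixel noise; `NULL`
#'   (default) renders the noiseless phantom.
#' @return `size x size` matrix in `[0, 1]`.
#' @export
make_image <- function(tau, spec, noise_seed = NULL) {
  n <- spec$size
  at <- blob_attributes(tau, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)     # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)    # row index
  d <- sqrt((xs - at$cx)^2 + (ys - at$cy)^2)
  img <- at$peak * pmin(pmax(at$r - d + 0.5, 0), 1) # disc with 1px soft edge
  if (!is.null(noise_seed) && spec$noise_sd > 0) {
    set.seed(as.integer(noise_seed))
    img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate the paired omics matrices for a factor matrix
#'
#' Each modality matrix is `factors %*% t(loadings_k) + noise`, where the
#' modality-specific loadings share one seeded Gaussian gene basis scaled by
#' per-modality factor weights: `loadings_k = B %*% diag(w_k)`. This plants
#' an exact rank-R trilinear (CP) signal — patient factors times gene basis
#' times modality weights — which is the generative model the tensor
#' factorization assumes, so the patient factors are recoverable from the
#' noisy tensor.
#'
#' @param factors `n_patients x R` matrix from [make_factors()].
#' @param spec a [fixture_spec()].
#' @return Named list of three [omics_matrix()] objects
#'   (expression, methylation, cnv).
#' @export
make_omics <- function(factors, spec) {
  mods <- c("expression", "methylation", "cnv")
  out <- vector("list", 3)
  names(out) <- mods
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  set.seed(derive_seed(spec$seed, 20))
  B <- matrix(stats::rnorm(spec$n_genes * spec$R), spec$n_genes, spec$R)
  w <- matrix(stats::runif(3 * spec$R, 0.5, 1.5), 3, spec$R)
  for (k in 1:3) {
    m <- factors %*% t(sweep(B, 2, w[k, ], "*"))
    if (spec$omics_noise_sd > 0) {
      set.seed(derive_seed(spec$seed, 20 + k))
      m <- m + matrix(stats::rnorm(length(m), sd = spec$omics_noise_sd),
                      nrow(m), ncol(m))
    }
    # values are centred (log-ratio-like); an intercept would add a rank-one
    # offset component and make the planted tensor rank R + 1
    dimnames(m) <- list(rownames(factors), gene_ids)
    out[[k]] <- omics_matrix(m, modality = mods[k])
  }
  out
}

#' Decode blob attributes from an image
#'
#' Measurement instrument for conditional generation: thresholds the image
#' at half its maximum, and reports the intensity-weighted centroid of the
#' suprathreshold pixels, the area-equivalent radius
#' \eqn{\sqrt{\mathrm{area}/\pi}}, and the peak intensity. An all-zero (or
#' all-subthreshold) image returns the defined null record (`NA` centroid,
#' zero radius and peak).
#'
#' @param img numeric matrix in `[0, 1]`.
#' @return List with `cx`, `cy`, `r`, `peak`.
#' @export
decode_image <- function(img) {
  peak <- max(img)
  if (peak <= 0)
    return(list(cx = NA_real_, cy = NA_real_, r = 0, peak = 0))
  mask <- img >= peak / 2
  w <- img * mask
  n <- nrow(img)
  xs <- matrix(rep(seq_len(ncol(img)), each = n), n, ncol(img))
  ys <- matrix(rep(seq_len(n), times = ncol(img)), n, ncol(img))
  tot <- sum(w)
  list(cx = sum(w * xs) / tot,
       cy = sum(w * ys) / tot,
       r = sqrt(sum(mask) / pi),
       peak = peak)
}

#' Generate a complete paired fixture set
#'
#' Draws factors, renders one image per patient (per-patient derived noise
#' seeds), and generates the three omics matrices.
#'
#' @param spec a [fixture_spec()].
#' @return List with `factors`, `images` (`size x size x n_patients` array,
#'   unit range), `omics` (list of three matrices), and `spec`.
#' @export
make_fixtures <- function(spec = fixture_spec()) {
  factors <- make_factors(spec)
  n <- spec$size
  imgs <- array(0, dim = c(n, n, spec$n_patients))
  for (i in seq_len(spec$n_patients))
    imgs[, , i] <- make_image(factors[i, ], spec,
                              noise_seed = derive_seed(spec$seed, 1000 + i))
  list(factors = factors, images = imgs, omics = make_omics(factors, spec),
       spec = spec)
}

#' Write a fixture set to disk
#'
#' Images go out as PNG plus the lossless float container; omics matrices
#' and factors as TSV.
#'
#' @param fx result of [make_fixtures()].
#' @param dir output directory (created if needed).
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(fx$images)[3])) {
    id <- rownames(fx$factors)[i]
    write_image_png(fx$images[, , i], file.path(dir, paste0(id, ".png")))
    write_image_float(fx$images[, , i], file.path(dir, paste0(id, ".txt")))
  }
  for (nm in names(fx$omics))
    write_omics_tsv(fx$omics[[nm]], file.path(dir, paste0(nm, ".tsv")))
  utils::write.table(data.frame(patient_id = rownames(fx$factors),
                                fx$factors),
                     file.path(dir, "factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
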