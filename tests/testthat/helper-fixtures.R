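# Shared fixtures: small colour templates, rendered ears and rectangle masks
# built in code at test time.

base_template <- function() {
  tibble::tibble(
    R = c(40, 150, 230), G = c(40, 75, 190), B = c(48, 50, 60),
    class = c("background", "cob", "kernel"))
}

# an ear_instance with a perfect rectangular silhouette; kernel rows can be
# painted as full-width horizontal bands
rect_ear <- function(length_cm = 20, width_cm = 5, px_per_cm = 10,
                     kernel_rows = NULL) {
  h <- round(length_cm * px_per_cm); w <- round(width_cm * px_per_cm)
  km <- matrix(FALSE, h, w)
  if (!is.null(kernel_rows)) km[kernel_rows, ] <- TRUE
  cm <- !km
  ear_instance(km, cm, px_per_cm)
}

# hybrids x traits matrix with `groups` well-separated trait families:
# orthonormal latent directions (equidistant group centroids) plus
# per-feature noise at 1/separation of the latent scale
three_group_traits <- function(n_hybrids = 120, groups = 3, per_group = 5,
                               separation = 10, seed = 1) {
  set.seed(seed)
  latent <- qr.Q(qr(matrix(rnorm(n_hybrids * groups), n_hybrids, groups))) *
    sqrt(n_hybrids)
  X <- latent[, rep(seq_len(groups), each = per_group)] +
    matrix(rnorm(n_hybrids * groups * per_group, 0, 1 / separation),
           n_hybrids)
  colnames(X) <- paste0("T", seq_len(ncol(X)))
  list(X = X, truth = rep(seq_len(groups), each = per_group))
}

# render one ear and wrap its ground-truth labels as an instance (bypasses
# classification so trait tests isolate the trait formulas)
rendered_ear <- function(spec = ear_spec(), px_per_cm = 20) {
  r <- render_ear(spec, px_per_cm = px_per_cm)
  list(ear = ear_instance(r$labels == 3L, r$labels == 2L, px_per_cm),
       truth = r$truth, sites = r$sites, render = r)
}
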