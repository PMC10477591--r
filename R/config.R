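#' Model and training configuration
#'
#' Collects every architecture and objective hyperparameter in one place.
#' Defaults follow the published setting where one is stated (latent size
#' K = 256, bottleneck weight beta = 1e-5, dropout 0.2, SiLU activations,
#' three fully connected layers, one 2-D convolution + max-pool front end on
#' the abundance view) and otherwise use conventional values, all
#' overridable.
#'
#' @param latent_dim K, dimension of the stochastic code U.
#' @param beta nonnegative weight of the KL compression term.
#' @param dropout_p dropout probability in `[0, 1)`, applied after each
#'   hidden fully connected layer during training only.
#' @param multi_view if `TRUE`, use the distance view alongside abundance.
#' @param use_conv if `TRUE`, the abundance view passes through a 2-D
#'   convolution + max-pool before the fully connected stack.
#' @param conv_channels number of convolution filters.
#' @param conv_kernel convolution kernel side (stride 1, size-preserving
#'   zero padding).
#' @param pool_size max-pooling window (non-overlapping).
#' @param hidden_sizes integer vector of the three hidden layer widths.
#' @param learning_rate Adam step size.
#' @param max_epochs epoch budget per fit.
#' @param patience early-stopping patience: a cross-validation fold stops
#'   when its validation AUC has not improved for this many epochs.
#' @param squared_distance if `TRUE`, the distance view carries squared
#'   Euclidean distances instead of Euclidean distances.
#' @param seed integer seed controlling initialization, dropout and the
#'   reparameterization noise.
#' @return A list of class `mvcvib_config`.
#' @export
mvcvib_config <- function(latent_dim = 256,
                          beta = 1e-5,
                          dropout_p = 0.2,
                          multi_view = TRUE,
                          use_conv = TRUE,
                          conv_channels = 8,
                          conv_kernel = 3,
                          pool_size = 2,
                          hidden_sizes = c(512, 256, 256),
                          learning_rate = 1e-3,
                          max_epochs = 200,
                          patience = 20,
                          squared_distance = FALSE,
                          seed = 42) {
  stopifnot(latent_dim >= 1, beta >= 0, dropout_p >= 0, dropout_p < 1,
            conv_channels >= 1, conv_kernel >= 1, pool_size >= 1,
            length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            learning_rate > 0, max_epochs >= 1, patience >= 1)
  structure(list(latent_dim = as.integer(latent_dim), beta = beta,
                 dropout_p = dropout_p, multi_view = isTRUE(multi_view),
                 use_conv = isTRUE(use_conv),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 squared_distance = isTRUE(squared_distance),
                 seed = as.integer(seed)),
            class = "mvcvib_config")
}

#' @export
print.mvcvib_config <- function(x, ...) {
  cat("<mvcvib_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm,
                                   paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
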