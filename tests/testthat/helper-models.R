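# A small trained nuclei model shared across tests in one session;
# trained lazily on first use (depth 2, base 8, 64x64 synthetic scenes).
.model_cache <- new.env(parent = emptyenv())

small_nuclei_model <- function() {
  if (is.null(.model_cache$nuclei)) {
    train <- lapply(1:8, nuclei_pair)
    val <- lapply(11:13, nuclei_pair)
    cfg <- unet_config("nuclei", input_size = c(64L, 64L), depth = 2L,
                       base_filters = 8L, batch_size = 2L, epochs = 8L,
                       seed = 21L)
    .model_cache$nuclei <- train_unet(build_unet(cfg), train, val)
  }
  .model_cache$nuclei
}
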