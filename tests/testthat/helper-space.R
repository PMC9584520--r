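# The pruned three-strain space is expensive enough to build once and share.
.space_cache <- new.env()
get_test_space <- function() {
  if (is.null(.space_cache$space))
    .space_cache$space <- three_strain_space()
  .space_cache$space
}
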