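# The in-silico block study is expensive (about two thousand paced-cell
# simulations), so it is computed once and shared by the acceptance blocks.

get_study <- function() {
  memo("block_study", simulateBlockStudy(nCells = 100, seed = 1))
}
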