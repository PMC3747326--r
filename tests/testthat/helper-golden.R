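# Frozen output of the first verified `gif` run on the packaged synthetic
# cohort (R = 50, seed = 1, subsets all + lethal). Guards against silent
# drift in the statistic, the matching, or the RNG stream.
golden_gif_results <- c(
  "group\tn\tcase_gif\tmean_control_gif\tempirical_p",
  "all\t28\t3127.07\t2367.13\t<0.02",
  "lethal\t13\t4652.44\t2415.16\t<0.02"
)
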