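policy,ssr,scr,mcr
doctor,1.39,1.59,1.42
dqn,3.03,5.86,6.96
drqn,3.52,6.24,7.18
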