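>t2
AATCATGAACCTCAGATTCCACCCACCCACCAACATAAAA
>t3
AATCATGAACCTCAGATTCCTCCAACCCACCAACATAAAA
>t1
AATCATGAACCTCAGATTCCACCAACCCACCAACCTAAAA
>t4
AATCATGAACCTCAGATTCCACCAACCCACTAACGTAAAA
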