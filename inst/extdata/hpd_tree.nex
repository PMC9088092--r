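#NEXUS
begin trees;
	translate
		1 A,
		2 B,
		3 C
		;
tree SUMMARY = [&R] ((1:5,2:5)[&age_95%_HPD={4,6}]:5,3:10)[&age_95%_HPD={8,12}];
end;
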