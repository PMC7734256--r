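# Tallied parental-constitution classes of 92 complete chromosome sets from
# karyotyped selfed progeny of a W22/B73 autotetraploid hybrid
# (W22 count first, B73 second).
class,count
4:0,6
3:1,20
2:2,41
1:3,23
0:4,2
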