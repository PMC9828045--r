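((((sp04:0.4991204095,(sp01:0.4054352732,sp02:0.4054352732):0.0936851363):0.9627594329,sp06:1.461879842):1.791615683,sp05:3.253495525):8.246504475,sp03:11.5);
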