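restype	residue	cluster	S1	S2	S3	S4	total_printed
K	C51	FX	-3.2	-2.6	-2.3	-1.8	-9.9
K	C51	FA	-5.5	-16.9	-5	-5.6	-33
K	C51	FB	-0.8	-0.7	-1.5	-1.2	-4.2
R	A583	FX	-3.5	-1.9	-1.8	-2.2	-9.4
R	A583	FA	-2.5	-4.1	-6.2	-4.3	-17
R	A583	FB			-0.5	-0.5	-1
R	C65	FX	-1.8	-2.2	-1.7	-1.3	-7
R	C65	FA	-2.1	-2.9	-1.4	-1.9	-8.3
R	C65	FB	-0.9	-1.1	-2.1	-1.6	-5.7
H	C2	FX	-1.4	-1	-1.1	-0.8	-4.3
H	C2	FA	-1.9	-2.7	-2.1	-1.3	-8
H	C2	FB					0
R	D60	FX	-1.1	-0.6	-0.7	-0.8	-3.2
R	D60	FA	-1.4	-1.6	-3.2	-1.6	-7.8
R	D60	FB					0
R	B674	FX	-4.1	-2.3	-3.3	-3.2	-13
R	B674	FA	-0.8	-1.5	-1.3	-0.9	-4.5
R	B674	FB					0
R	B570	FX	-1.5	-2.2	-1.5	-1.2	-6.4
R	B570	FA	-0.9	-1.4	-0.7	-1.1	-4.1
R	B570	FB	-0.5	-0.8	-1	-1	-3.3
K	D61	FX					0
K	D61	FA	-2.3	-1.3	-2.7	-1.7	-8
K	D61	FB	-0.5		-0.5		-1
R	B18	FX	-1.6	-1.1	-1.6	-1.2	-5.5
R	B18	FA	-0.7	-1.2	-0.8	-0.6	-3.3
R	B18	FB					0
R	C43	FX					0
R	C43	FA	-2.1	-1	-1.6	-1.2	-5.9
R	C43	FB	-0.7		-0.7	-0.5	-1.9
K	A569	FX	-2.4	-1.6	-1.6	-2.5	-8.1
K	A569	FA	-0.6	-0.9	-1.1	-0.9	-3.5
K	A569	FB					0
K	D134	FX	-0.7	-0.6	-0.8	-0.5	-2.6
K	D134	FA		-0.7			-0.7
K	D134	FB					0
R	C74	FX					0
R	C74	FA	-0.8	-0.7	-1.4	-0.6	-3.5
R	C74	FB					0
R	A694	FX	-2.1	-4	-2.6	-3.1	-12
R	A694	FA		-0.6		-0.5	-1.1
R	A694	FB					0
K	A555	FX	-2	-1.4	-1.7	-2.3	-7.4
K	A555	FA		-0.6	-0.7	-0.6	-1.9
K	A555	FB					0
K	B556	FX	-1.7	-2.3	-2.9	-1.9	-8.8
K	B556	FA		-0.6			-0.6
K	B556	FB					0
R	A437	FX	-0.8	-0.6	-0.6	-0.9	-2.9
R	A437	FA		-0.5	-0.6	-0.5	-1.6
R	A437	FB					0
R	A564	FX	-0.7	-0.5	-0.5	-0.7	-2.4
R	A564	FA		-0.5	-0.7		-1.2
R	A564	FB					0
R	B399	FX	-0.7	-0.6	-0.9	-0.6	-2.8
R	B399	FA		-0.5			-0.5
R	B399	FB					0
T	C22	FX					0
T	C22	FA	-0.5	-0.5	-3	-0.5	-4.5
T	C22	FB					0
T	A586	FX	-1.7				-1.7
T	A586	FA					0
T	A586	FB					0
K	B542	FX	-1.3	-1.8	-2.3	-1.7	-7.1
K	B542	FA					0
K	B542	FB					0
H	A734	FX	-0.9	-1.1	-1.2	-1.6	-4.8
H	A734	FA					0
H	A734	FB					0
R	A575	FX	-0.8	-0.9	-0.7	-1.1	-3.5
R	A575	FA					0
R	A575	FB					0
R	B712	FX	-0.8	-0.8	-5.2	-1.3	-8.1
R	B712	FA					0
R	B712	FB					0
R	A720	FX	-0.7	-1.3	-0.9	-1	-3.9
R	A720	FA					0
R	A720	FB					0
R	A728	FX	-0.7		-0.5	-1.9	-3.1
R	A728	FA					0
R	A728	FB					0
H	B392	FX	-0.7	-0.6	-0.9	-0.6	-2.8
H	B392	FA					0
H	B392	FB					0
H	A411	FX	-0.6	-0.6	-0.6	-0.8	-2.6
H	A411	FA					0
H	A411	FB					0
H	B28	FX	-0.5		-0.7	-0.5	-1.7
H	B28	FA					0
H	B28	FB					0
K	B418	FX	-0.5	-0.6	-0.7	-0.5	-2.3
K	B418	FA					0
K	B418	FB					0
R	A418	FX				-0.5	-0.5
R	A418	FA					0
R	A418	FB					0
H	A542	FX				-0.5	-0.5
H	A542	FA					0
H	A542	FB					0
H	A56	FX		-0.5		-0.6	-1.1
H	A56	FA					0
H	A56	FB					0
H	B534	FX			-0.5	-0.5	-1
H	B534	FA					0
H	B534	FB					0
T	B573	FX		-1.9			-1.9
T	B573	FA					0
T	B573	FB					0
I	B708	FX			-0.5		-0.5
I	B708	FA					0
I	B708	FB					0
Q	C15	FX					0
Q	C15	FA					0
Q	C15	FB	-0.5	-0.5		-1.2	-2.2
R	C18	FX					0
R	C18	FA	-0.5		-0.5	-0.7	-1.7
R	C18	FB	-0.6			-0.5	-1.1
K	C5	FX					0
K	C5	FA	-0.5				-0.5
K	C5	FB			-0.5
T	C55	FX					0
T	C55	FA					0
T	C55	FB					0
T	C59	FX					0
T	C59	FA					0
T	C59	FB		-0.6	-0.5		-1.1
I	C64	FX					0
I	C64	FA					0
I	C64	FB			-0.5		-0.5
R	D109	FX					0
R	D109	FA	-0.6				-0.6
R	D109	FB	-1		-0.6	-0.5	-2.1
N	D113	FX					0
N	D113	FA	-0.6				-0.6
N	D113	FB					0
K	D26	FX					0
K	D26	FA					0
K	D26	FB					0
R	D73	FX					0
R	D73	FA	-0.6		-0.6	-0.7	-1.9
R	D73	FB					0
R	D84	FX					0
R	D84	FA	-0.5		-0.7		-1.2
R	D84	FB					0
R	E11	FX					0
R	E11	FA					0
R	E11	FB	-0.5	-1.2	-0.8	-0.6	-3.1
K	E33	FX					0
K	E33	FA					0
K	E33	FB	-0.5	-0.8	-0.7		-2
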